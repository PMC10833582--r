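source_label,source_currency,target_year,factor,provenance
Wouters2020,USD,2015,0.850723859500,derived: published adjusted/unadjusted input pair
Wouters2020,USD,2014,0.709650093921,derived: published adjusted/unadjusted input pair
Nosengo2016,USD,2015,0.890067480000,derived: published adjusted/unadjusted input pair
Nosengo2016,USD,2014,0.742469446667,derived: published adjusted/unadjusted input pair
OuYang2019,USD,2015,0.835490196078,derived: published adjusted/unadjusted input pair
OuYang2019,USD,2014,0.697058823529,derived: published adjusted/unadjusted input pair
Kelly2009,USD,2015,0.995769230769,derived: published adjusted/unadjusted input pair
Kelly2009,USD,2014,0.830384615385,derived: published adjusted/unadjusted input pair
AIM,USD,2015,0.850723859500,derived: published adjusted/unadjusted input pair
AIM,USD,2014,0.709650093921,derived: published adjusted/unadjusted input pair
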