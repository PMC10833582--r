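source_label,label,unadjusted,adjusted_y1,adjusted_y2
Wouters2020,crd_base,4461200000,3795249282,3165890999
Wouters2020,crd_low_ci,3.114e+09,2649154098,2209850393
Wouters2020,crd_high_ci,6001300000,5105449097,4258823109
Wouters2020,crd_uncapitalized,1.032e+09,877947023,732358897
Nosengo2016,cex_base,3e+08,267020244,222740834
AIM,cex_aim,446120000,379524928,316589100
OuYang2019,cman_base,51,42.61,35.55
Kelly2009,cman_low,26,25.89,21.59
Kelly2009,cman_high,134,133.43,111.3
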