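scenario,source_label,parameter,unadjusted
1,Wouters2020,crd,3.114e+09
2,Wouters2020,crd,6001300000
3,Wouters2020,crd,1.032e+09
4,AIM,cex,446120000
5,Kelly2009,cman,26
6,Kelly2009,cman,134
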