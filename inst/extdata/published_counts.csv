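variable,level,n
hiv_test,never,250
hiv_test,negative,1510
hiv_test,positive,792
art_initiated,yes,785
art_initiated,no,7
prep_current,no,1534
prep_current,yes,226
uu_completely_accurate,yes,1600
uu_completely_accurate,no,952
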