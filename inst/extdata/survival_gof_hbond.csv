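ranking,tsp8_resid,tsp8_resno,spacer_resid,spacer_resno,spacer_exosite,rep1,rep2,rep3,mean_printed,sem_printed
1,ARG,1075,ASP,635,4,0.992,0.893,0.621,0.835,0.091
2,ARG,1095,ASP,635,4,0.844,0.000,0.910,0.585,0.239
3,ARG,1075,GLU,634,4,0.668,0.414,0.137,0.406,0.125
4,CYS,1130,ARG,636,4,0.987,0.079,0.000,0.356,0.259
5,ARG,1123,ASP,635,4,0.000,0.000,0.771,0.257,0.210
6,TRP,1081,ASP,635,4,0.618,0.000,0.000,0.206,0.168
7,VAL,1120,TYR,592,3,0.000,0.000,0.386,0.129,0.105
8,ALA,1127,HSD,594,NA,0.000,0.304,0.000,0.101,0.083
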