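ranking,tsp8_resid,tsp8_resno,spacer_resid,spacer_resno,spacer_exosite,rep1,rep2,rep3,mean_printed,sem_printed
1,ARG,1075,ASP,635,4,0.652,0.911,0.883,0.815,0.067
2,ARG,1095,ASP,635,4,0.843,0.930,0.000,0.591,0.242
3,CYS,1130,ARG,636,4,0.051,0.423,0.681,0.385,0.149
4,ASP,1090,ARG,660,3,0.000,0.938,0.000,0.313,0.255
5,ARG,1095,GLU,634,4,0.000,0.000,0.915,0.305,0.249
6,CYS,1125,TYR,661,3,0.718,0.161,0.000,0.293,0.178
7,ASP,1090,ARG,568,3,0.446,0.336,0.000,0.261,0.109
8,CYS,1125,ARG,660,3,0.000,0.754,0.000,0.251,0.205
9,ASP,1090,TYR,661,3,0.000,0.703,0.000,0.234,0.191
10,CYS,1130,ARG,660,3,0.000,0.000,0.646,0.215,0.176
11,ASP,1090,TYR,665,3,0.466,0.000,0.000,0.155,0.127
12,ARG,1075,GLU,634,4,0.285,0.097,0.000,0.127,0.068
13,CYS,1084,TYR,665,3,0.365,0.000,0.000,0.122,0.099
14,GLY,1091,TYR,665,3,0.353,0.000,0.000,0.118,0.096
15,HIS,1115,ARG,639,4,0.350,0.000,0.000,0.117,0.095
16,CYS,1130,TYR,665,3,0.000,0.314,0.000,0.105,0.085
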