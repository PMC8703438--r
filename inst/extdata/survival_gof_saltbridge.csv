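ranking,tsp8_resid,tsp8_resno,spacer_resid,spacer_resno,spacer_exosite,rep1,rep2,rep3,mean_printed,sem_printed
1,ARG,1075,ASP,635,4,0.666,0.950,0.450,0.689,0.118
2,ARG,1075,GLU,634,4,0.000,0.000,0.858,0.286,0.233
3,ASP,1090,LYS,660,3,0.000,0.500,0.000,0.167,0.136
4,ASP,1090,LYS,568,3,0.000,0.467,0.000,0.156,0.127
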