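ranking,tsp8_resid,tsp8_resno,spacer_resid,spacer_resno,spacer_exosite,rep1,rep2,rep3,mean_printed,sem_printed
1,ARG,1075,ASP,635,4,0.560,0.985,0.943,0.829,0.110
2,ARG,1095,ASP,635,4,0.716,0.993,0.000,0.569,0.241
3,ARG,1095,GLU,634,4,0.000,0.000,0.989,0.330,0.269
4,ASP,1090,ARG,660,3,0.000,0.960,0.000,0.320,0.261
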