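ranking,tsp8_resid,tsp8_resno,spacer_resid,spacer_resno,spacer_exosite,rep1,rep2,rep3,mean_printed,sem_printed
1,GLY,1128,SER,612,NA,0.900,0.000,0.000,0.300,0.212
2,CYS,1125,LEU,591,NA,0.000,0.718,0.000,0.239,0.169
3,ALA,1090,TYR,661,3,0.101,0.413,0.068,0.194,0.078
4,GLY,1124,LEU,591,NA,0.546,0.000,0.000,0.182,0.129
5,CYS,1125,TYR,661,3,0.492,0.000,0.000,0.164,0.116
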