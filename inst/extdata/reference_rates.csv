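# units: percent
cell_type,rate,controls,RRMS_naive,RRMS_NAT,RRMS_ALEM,SuS
CD4,alpha1,0.111389,0.586281,0.0532484,0.796713,0.200412
CD4,alpha2,0.0911057,0.472904,0.104328,0.579225,0.14176
CD4,beta1,6.36074,6.97785,5.56686,16.5061,9.53956
CD4,beta2,4.94663,5.36697,9.84513,10.7709,6.32671
CD8,alpha1,0.120849,0.743036,0.16279,1.38373,0.144033
CD8,alpha2,0.280367,1.68937,0.383813,2.36217,0.196247
CD8,beta1,10.5938,12.6372,8.48535,22.0888,22.3179
CD8,beta2,19.7744,22.4608,16.7073,27.9459,23.472
B,alpha1,0.00624261,0.163174,0.00734096,0.114144,0.034936
B,alpha2,0.517731,2.05505,0.756185,4.19525,0.628489
B,beta1,0.512537,0.706717,0.539675,0.290181,1.07631
B,beta2,29.9383,8.32669,35.9123,10.0614,16.3201
NK,alpha1,0.00960978,0.083438,0.00982681,0.143154,0.012265
NK,alpha2,0.0035751,0.008764,0.00583337,0.013084,0.007612
NK,beta1,93.6461,92.5525,88.5722,78.6259,92.6465
NK,beta2,25.7994,8.89219,34.558,6.71746,36.57
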