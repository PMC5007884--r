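c_pcr_exp,mean_positive,mean_negative,mean_rain,s_thres_rel_pct
5400,18046,414,95.9,3.0
2575,16005,2530,39.0,0.5
255,3488,16248,14.3,0.3
26,397,19457,4.1,0.8
2.5,38,19708,3.6,7.2
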