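sample,annealing_temp_c,primer_nM,probe_nM,c_pcr_mean,c_pcr_sd
AD623d,60,300,200,279,5
AD623d,60,330,220,273,4
AD623d,60,270,180,285,8
AD623c,59,300,200,2946,54
AD623c,60,300,200,2954,35
AD623c,61,300,200,2948,68
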