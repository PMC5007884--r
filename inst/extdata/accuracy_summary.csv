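level_id,c_cert,U_cert,c_meas,bias_rel_pct,s_repeat_rel_pct,s_run_rel_pct,u_precision_rel_pct,run_clamped
AD623a,1.08e6,0.13e6,0.97e6,-10.2,4.7,1.4,1.1,FALSE
AD623b,1.08e5,0.11e5,0.93e5,-13.8,5.6,5.3,3.2,FALSE
AD623c,1.03e4,0.10e4,0.94e4,-9.0,4.8,2.7,1.8,FALSE
AD623d,1.02e3,0.09e3,0.93e3,-8.5,7.7,0,1.2,TRUE
AD623e,104,10,97,-7.0,7.3,2.0,1.6,FALSE
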