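level_id,c_cert,U_cert
AD623a,1.08e6,0.13e6
AD623b,1.08e5,0.11e5
AD623c,1.03e4,0.10e4
AD623d,1.02e3,0.09e3
AD623e,104,10
AD623f,10.0,1.5
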