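days_before_eclosion,x_r1,y_r2a,z_fsc
2,20,37,69
3,41,46,93
4,156,80,134
5,191,140,164
6,356,253,295
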