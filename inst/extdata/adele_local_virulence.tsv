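moi	local_virulence
1e-07	0.17
1e-06	0.16
1e-05	0.20
1e-04	0.25
1e-03	0.68
0.01	0.97
0.1	0.92
1	0.97
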