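1
0.06
0.02
0.02
0.01
0.005
0.005
0.005
0.001
0.001
0.001
0.0005
0.0005
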