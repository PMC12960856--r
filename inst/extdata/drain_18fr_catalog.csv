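flow_l_min,pressure_mmhg
0.5,2.9
1,7.1
1.5,12.6
2,19.4
2.5,27.5
3,36.9
3.5,47.6
4,59.6
4.5,72.9
5,87.5
5.5,103.4
6,120.6
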