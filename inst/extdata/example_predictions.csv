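"p","y"
0.3567,0
0.106,0
0.3039,1
0.2831,0
0.1231,0
0,0
0.1971,0
0.0724,0
0.275,1
0.2002,0
0.2162,0
0.1438,0
0.2629,0
0.2207,1
0.0158,0
0.6428,1
0.4677,0
0.2892,0
0.1197,0
0.4593,1
0.241,0
0.2092,0
0.0485,0
0.6175,0
0.3439,0
0.3011,0
0.4594,0
0.7589,1
0.1771,0
0.3402,0
0.2654,0
0.3104,1
0.2864,0
0.5767,1
0.4642,0
0.0994,0
0.3791,0
0.1349,0
0.0621,0
0.3466,0
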