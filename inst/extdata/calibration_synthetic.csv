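# synthetic dose-response calibration: logistic-saturation stand-in
# f(C) = 0.7 * C / (C + 1 uM); nonfret_fraction = 1 - f(C)
# not measured data
#bleed_coeff=0.01
#tau_long_ps=2460
#tau_short_ps=770
concentration_uM,nonfret_fraction
0,1
0.18,0.89322
0.9,0.668421
1.8,0.55
9,0.37
18,0.336842
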