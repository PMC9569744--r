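# 5-point piecewise-linear approximation of an 18 cm pH 3-11 NL gradient
# position in cm from the acidic end
position	pH
0	3
4.5	4.8
9	6.0
13.5	7.6
18	11
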