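# broad-range SDS-PAGE marker ladder, 14% gel
# migration is the fraction of the separation distance
migration	mw
0.05	250000
0.13	150000
0.22	100000
0.33	75000
0.47	50000
0.62	37000
0.78	25000
0.87	20000
0.95	15000
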