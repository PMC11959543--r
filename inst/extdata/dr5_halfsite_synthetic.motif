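>AGGTCANNNNNAGGTCA	DR5	NA	6	5
0.70	0.05	0.20	0.05
0.05	0.05	0.80	0.10
0.05	0.05	0.75	0.15
0.05	0.05	0.10	0.80
0.10	0.75	0.05	0.10
0.80	0.05	0.05	0.10
0.30	0.20	0.20	0.30
0.25	0.25	0.25	0.25
0.30	0.25	0.20	0.25
0.25	0.20	0.25	0.30
0.30	0.20	0.25	0.25
0.70	0.05	0.20	0.05
0.05	0.05	0.80	0.10
0.05	0.05	0.75	0.15
0.05	0.05	0.10	0.80
0.10	0.75	0.05	0.10
0.80	0.05	0.05	0.10
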