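Sample	Dye	Marker	Allele	Size	Height	Area	Data Point
NEG_01	B			95.12	6	31	1951
NEG_01	B			120.05	14	70	2200
NEG_01	B			233.40	9	44	3334
NEG_01	G			101.77	12	60	2017
NEG_01	G			310.02	21	105	4100
NEG_01	O			120.00	3050	15300	2199
NEG_02	B			140.90	11	52	2409
NEG_02	B			402.33	7	36	5023
NEG_02	G			87.50	18	91	1875
NEG_02	G			255.01	10	48	3550
NEG_02	O			160.00	2980	14800	2600
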