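year	quarter	lab	kit	n_samples
2019	S4	LAB_f	PowerPlex21	17
2020	S1	LAB_a	AGCU_EX22	4
2020	S1	LAB_c	VeriFilerPlus	32
2020	S1	LAB_e	PowerPlex21	11
2020	S1	LAB_f	PowerPlex21	6
2020	S2	LAB_a	AGCU_EX22	25
2020	S2	LAB_c	PowerPlex21	50
2020	S2	LAB_d	PowerPlex21	8
2020	S2	LAB_e	PowerPlex21	8
2020	S2	LAB_e	VeriFilerPlus	5
2020	S2	LAB_f	PowerPlex21	4
2020	S3	LAB_a	AGCU_EX22	23
2020	S3	LAB_c	PowerPlex21	35
2020	S3	LAB_d	PowerPlex21	6
2020	S3	LAB_e	PowerPlex21	13
2020	S3	LAB_f	PowerPlex21	7
2020	S4	LAB_a	AGCU_EX22	26
2020	S4	LAB_c	PowerPlex21	39
2020	S4	LAB_d	PowerPlex21	10
2020	S4	LAB_e	PowerPlex21	11
2020	S4	LAB_f	PowerPlex21	5
2021	S1	LAB_a	AGCU_EX22	29
2021	S1	LAB_c	PowerPlex21	34
2021	S1	LAB_d	PowerPlex21	17
2021	S1	LAB_e	PowerPlex21	10
2021	S1	LAB_f	PowerPlex21	5
2021	S2	LAB_a	AGCU_EX22	23
2021	S2	LAB_c	PowerPlex21	23
2021	S2	LAB_d	PowerPlex21	7
2021	S2	LAB_e	PowerPlex21	12
2021	S2	LAB_f	PowerPlex21	6
2021	S3	LAB_a	AGCU_EX22	26
2021	S3	LAB_b	VeriFilerPlus	7
2021	S3	LAB_c	VeriFilerPlus	31
2021	S3	LAB_d	PowerPlex21	12
2021	S3	LAB_e	VeriFilerPlus	7
2021	S3	LAB_f	PowerPlex21	6
2021	S4	LAB_a	AGCU_EX22	21
2021	S4	LAB_b	VeriFilerPlus	12
2021	S4	LAB_c	VeriFilerPlus	17
2021	S4	LAB_d	PowerPlex21	16
2021	S4	LAB_e	VeriFilerPlus	9
2021	S4	LAB_f	PowerPlex21	4
2022	S1	LAB_a	AGCU_EX22	26
2022	S1	LAB_b	VeriFilerPlus	10
2022	S1	LAB_c	VeriFilerPlus	56
2022	S1	LAB_e	VeriFilerPlus	14
2022	S1	LAB_f	PowerPlex21	8
2022	S2	LAB_a	AGCU_EX22	21
2022	S2	LAB_b	VeriFilerPlus	17
2022	S2	LAB_d	PowerPlex21	25
2022	S2	LAB_e	VeriFilerPlus	12
2022	S3	LAB_a	AGCU_EX22	20
2022	S3	LAB_d	PowerPlex21	8
2022	S4	LAB_a	AGCU_EX22	25
2022	S4	LAB_d	PowerPlex21	8
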