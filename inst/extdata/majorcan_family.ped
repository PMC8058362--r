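FAM1	2	0	0	1	1
FAM1	SCA-3	0	0	2	2
FAM1	SCZ-7	2	SCA-3	1	2
FAM1	SCZ-8	2	SCA-3	1	2
FAM1	SCA-9	2	SCA-3	1	2
FAM1	10	2	SCA-3	2	1
FAM1	11	2	SCA-3	2	1
FAM1	14	0	0	1	1
FAM1	4	0	0	2	1
FAM1	13	14	4	1	1
FAM1	5	0	0	1	3
FAM1	6	0	0	2	3
FAM1	BD-12	5	6	2	2
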