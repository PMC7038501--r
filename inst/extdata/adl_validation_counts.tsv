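adl	subject	task	correct	total	subject_sp_printed
curve	1	1	28	29	98.85
curve	1	2	23	23	98.85
curve	1	3	26	26	98.85
curve	2	1	34	34	100.00
curve	2	2	36	36	100.00
curve	2	3	35	35	100.00
curve	3	1	51	51	100.00
curve	3	2	48	48	100.00
curve	3	3	49	49	100.00
tug	1	1	39	40	97.52
tug	1	2	55	56	97.52
tug	1	3	62	64	97.52
tug	2	1	47	48	99.30
tug	2	2	56	56	99.30
tug	2	3	48	48	99.30
tug	3	1	64	64	100.00
tug	3	2	64	64	100.00
tug	3	3	72	72	100.00
obstacle	1	1	40	42	97.48
obstacle	1	2	71	72	97.48
obstacle	1	3	63	64	97.48
obstacle	2	1	30	30	98.61
obstacle	2	2	35	36	98.61
obstacle	3	1	30	30	99.21
obstacle	3	2	41	42	99.21
obstacle	3	3	36	36	99.21
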