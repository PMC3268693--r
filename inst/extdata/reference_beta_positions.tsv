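crystal	position	mosaicity_deg	snr_first	snr_last	beta
thermolysin	1	0.56	5.2	2.0	0.74
thermolysin	2	0.51	3.9	1.6	0.82
thermolysin	3	0.53	4.6	2.3	0.67
trypsin	1	0.54	12.1	5.1	0.66
trypsin	2	0.61	13.4	5.2	0.71
trypsin	3	0.69	15.2	5.5	0.77
trypsin	4	0.63	16.8	6.3	0.72
trypsin	5	0.53	13.4	5.6	0.75
trypsin	6	0.63	15.8	7.3	0.65
A-DNA	1	0.32	13.3	8.1	0.80
A-DNA	2	0.40	8.6	6.6	0.81
A-DNA	3	0.46	8.8	7.6	0.86
FAE 1	1	0.25	9.1	3.6	0.90
FAE 1	2	0.23	9.0	3.6	0.89
FAE 1	3	0.17	6.5	3.4	0.90
FAE 2	1	0.31	9.3	3.9	0.80
FAE 2	2	0.27	12.5	4.5	0.81
FAE 2	3	0.25	7.4	2.1	1.02
RecR	1	0.88	4.3	1.9	0.86
RecR	2	0.90	5.1	2.7	0.68
RecR	3	0.60	4.5	1.9	0.74
RecR	4	0.86	3.9	1.9	0.85
GPCR	1	0.80	15.1	6.8	0.62
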