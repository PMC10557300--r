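family	role	selection	TN	FP	FN	TP	accuracy	precision	recall	f_measure
naive_bayes	caregiver	with_z	95	8	44	59	0.75	0.88	0.57	0.69
naive_bayes	caregiver	without_z	98	5	48	55	0.74	0.92	0.53	0.67
naive_bayes	patient	with_z	18	1	7	12	0.79	0.92	0.63	0.75
naive_bayes	patient	without_z	19	0	8	11	0.79	1.00	0.58	0.73
svm	caregiver	with_z	79	24	24	79	0.77	0.77	0.77	0.77
svm	caregiver	without_z	87	16	28	75	0.79	0.82	0.73	0.77
svm	patient	with_z	16	3	4	15	0.82	0.83	0.79	0.81
svm	patient	without_z	18	1	6	13	0.82	0.93	0.68	0.79
random_forest	caregiver	with_z	90	13	36	67	0.76	0.84	0.65	0.73
random_forest	caregiver	without_z	93	10	37	66	0.77	0.87	0.64	0.74
random_forest	patient	with_z	14	5	4	15	0.76	0.75	0.79	0.77
random_forest	patient	without_z	19	0	6	13	0.84	1.00	0.68	0.81
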