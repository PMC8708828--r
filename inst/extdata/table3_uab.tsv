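receptor	ligand	elect	elect_sd	vdw	vdw_sd	total	total_sd
CCD4a	3ON	-116.50	23.93	-274.37	16.58	-390.87	23.61
CCD4a	ACR	-33.11	10.16	-344.21	18.75	-377.32	22.07
CCD4a	BCR	-21.03	8.75	-344.23	17.66	-365.26	19.51
CCD4a	LYC	-32.66	10.96	-351.83	15.51	-384.49	18.94
CCD4a	LUT	-110.95	21.48	-342.63	17.54	-453.58	23.83
CCD4a	RRX	-77.24	16.85	-333.07	17.81	-410.30	21.77
CCD4a	ZEX	-135.94	25.19	-316.85	18.62	-452.79	26.42
CCD4b	3ON	-124.99	27.10	-271.27	18.53	-396.27	24.13
CCD4b	ACR	-33.41	10.80	-351.57	16.37	-384.97	21.24
CCD4b	BCR	-31.76	10.65	-342.07	14.83	-373.83	18.16
CCD4b	LYC	-32.05	10.86	-367.96	15.46	-400.02	19.02
CCD4b	LUT	-119.87	23.65	-331.35	17.78	-451.22	24.61
CCD4b	RRX	-76.22	12.89	-350.70	15.71	-426.93	20.45
CCD4b	ZEX	-121.58	25.71	-348.27	18.43	-469.85	26.72
CCD4c	3ON	-137.52	25.04	-257.66	16.61	-395.18	24.23
CCD4c	ACR	-29.88	10.07	-355.33	14.78	-385.21	17.95
CCD4c	BCR	-32.91	11.40	-346.46	16.16	-379.36	21.21
CCD4c	LYC	-36.42	11.65	-363.98	17.23	-400.40	19.95
CCD4c	LUT	-137.28	28.76	-318.32	18.68	-455.60	26.78
CCD4c	RRX	-83.85	18.59	-329.94	18.81	-413.79	23.63
CCD4c	ZEX	-132.90	23.44	-360.72	18.69	-493.62	24.86
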