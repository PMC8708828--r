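receptor	ligand	C7	C8	C9	C10	C15	C15P	mmpbsa	mmpbsa_sd
CCD4a	ACR	9.3	8.7	8.4	8.2	10.6	11.9	-148.50	14.88
CCD4a	BCR	8.2	7.1	6.3	6.0	8.0	9.2	-162.54	17.60
CCD4a	LUT	9.5	8.5	8.6	8.3	11.2	11.9	-136.63	17.78
CCD4a	RRX	7.4	7.3	7.3	8.4	10.9	11.2	-133.16	18.15
CCD4a	ZEX	7.8	7.04	6.5	7.4	10.2	11.1	-124.20	17.85
CCD4b	ACR	11.8	12.3	12.2	11.4	11.7	11.7	-123.18	17.91
CCD4b	BCR	11.1	11.2	10.7	9.5	9.4	10	-142.60	19.08
CCD4b	LUT	7.5	7.1	6.5	7.3	9.5	10.6	-119.18	29.12
CCD4b	RRX	10.1	9.9	8.9	7.8	5.8	6.8	-150.19	16.83
CCD4b	RRX*	8.9	8.0	6.8	6.9	7.9	8.6	-164.57	15.74
CCD4b	ZEX	7.0	6.7	6.2	7.1	10	11	-88.43	22.31
CCD4c	ACR	12.3	12	11.3	10	7.9	7.3	-106.32	19.08
CCD4c	BCR	10.9	9.9	8.5	8.2	5.8	6.3	-92.58	27.12
CCD4c	LUT	11.4	12.2	11.9	11.6	11.6	11.3	-105.77	28.35
CCD4c	RRX	10.8	11.2	10.5	9.8	8.7	9.12	-128.21	20.68
CCD4c	ZEX	12.2	11.14	9.93	8.8	6.4	6.8	-99.74	19.03
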