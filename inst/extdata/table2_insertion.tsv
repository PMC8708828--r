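protein	angle_deg	angle_sd	depth	depth_sd	dg_transfer
CCD4a	32	4	7.0	0.6	-64.4
CCD4b	39	4	5.8	1.3	-61.5
CCD4c	28	4	5.2	0.5	-48.5
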