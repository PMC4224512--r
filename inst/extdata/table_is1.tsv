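mirna	p_value	log10_rq	ct_status
mmu-miR-376a	9.43E-04	1.99	calibrator_not_detected
mmu-miR-494	1.85E-04	1.94	calibrator_not_detected
mmu-miR-297a#	3.11E-02	1.56	calibrator_not_detected
rno-miR-345-3p	4.78E-03	1.08	calibrator_not_detected
hsa-miR-214	1.82E-03	0.58	valid
mmu-miR-214	6.37E-03	0.54	valid
mmu-miR-337-5p	2.10E-02	0.52	valid
mmu-miR-574-3p	2.16E-02	0.51	valid
mmu-miR-434-3p	2.16E-02	0.41	valid
mmu-miR-671-3p	1.76E-02	0.39	valid
mmu-miR-218	4.46E-02	0.36	valid
mmu-miR-676	1.58E-02	0.33	valid
mmu-miR-199a-3p	3.34E-02	0.32	valid
hsa-miR-455	4.71E-02	0.28	valid
mmu-miR-322	9.85E-03	-0.34	valid
mmu-miR-331-3p	1.99E-02	-0.35	valid
hsa-miR-106b#	2.80E-02	-0.40	valid
mmu-miR-106b	1.41E-02	-0.47	valid
mmu-miR-2138	5.83E-03	-0.61	valid
mmu-miR-31	2.16E-02	-0.85	valid
mmu-miR-363	4.59E-02	-1.40	target_not_detected
mmu-miR-181c	2.86E-02	-1.66	target_not_detected
rno-miR-196c	4.66E-02	-1.81	target_not_detected
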