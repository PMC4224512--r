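mirna	p_value	log10_rq	ct_status
mmu-miR-700	2.31E-02	2.21	calibrator_not_detected
mmu-miR-487b	2.17E-03	1.91	calibrator_not_detected
mmu-miR-376a	1.11E-03	1.70	calibrator_not_detected
mmu-miR-125b	4.32E-02	1.23	calibrator_not_detected
mmu-miR-1932	2.25E-02	1.17	calibrator_not_detected
mmu-miR-218-1	3.42E-02	1.05	calibrator_not_detected
mmu-miR-191*	1.79E-02	1.00	calibrator_not_detected
mmu-miR-384-5p	6.70E-03	0.73	valid
hsa-miR-214	2.58E-05	0.72	valid
mmu-miR-667	5.12E-03	0.69	valid
mmu-miR-218	1.82E-04	0.64	valid
mmu-miR-214	8.97E-05	0.64	valid
mmu-miR-434-3p	3.91E-03	0.61	valid
mmu-miR-122	1.59E-03	0.61	valid
mmu-miR-34b-3p	3.05E-03	0.60	valid
mmu-miR-872*	9.36E-03	0.56	valid
mmu-miR-361	8.35E-03	0.55	valid
mmu-miR-485-3p	2.64E-02	0.53	valid
mmu-miR-574-3p	2.61E-03	0.53	valid
hsa-miR-9*	4.56E-02	0.52	valid
mmu-miR-337-5p	9.90E-03	0.49	valid
mmu-miR-685	3.22E-03	0.48	valid
mmu-miR-204	1.44E-02	0.44	valid
mmu-miR-376c	2.57E-02	0.43	valid
mmu-miR-199a-3p	2.91E-03	0.42	valid
mmu-miR-337-3p	2.11E-02	0.40	valid
mmu-miR-132	4.27E-02	0.40	valid
mmu-miR-671-3p	1.04E-02	0.37	valid
mmu-miR-152	1.58E-02	0.36	valid
mmu-miR-376b*	1.29E-02	0.34	valid
mmu-miR-212	3.85E-02	0.32	valid
mmu-miR-511	1.48E-02	0.31	valid
mmu-miR-192	2.19E-03	0.30	valid
mmu-miR-145	2.81E-02	0.25	valid
mmu-miR-146a	3.56E-02	0.24	valid
mmu-miR-19b	3.57E-02	-0.25	valid
mmu-miR-322	3.22E-02	-0.26	valid
hsa-miR-200c	1.20E-02	-0.26	valid
mmu-miR-486	2.56E-02	-0.27	valid
mmu-miR-1274a	3.52E-02	-0.28	valid
hsa-miR-200b	4.62E-02	-0.30	valid
mmu-miR-2146	2.90E-02	-0.30	valid
mmu-miR-652	1.91E-02	-0.30	valid
mmu-miR-18a	2.17E-02	-0.34	valid
hsa-miR-106b*	9.68E-03	-0.38	valid
mmu-miR-451	1.48E-02	-0.42	valid
mmu-miR-106b	7.93E-03	-0.45	valid
mmu-miR-26b	3.19E-02	-0.53	valid
mmu-miR-31	1.86E-02	-1.03	valid
hsa-miR-875-5p	4.14E-02	-3.02	valid
rno-miR-196c	4.67E-02	-1.53	target_not_detected
mmu-miR-1982.2	3.95E-02	-1.56	target_not_detected
mmu-miR-7a	8.20E-03	-1.98	target_not_detected
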