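mirna	p_value	log10_rq	ct_status
mmu-miR-15a*	2.14E-13	4.47	calibrator_not_detected
mmu-miR-129-3p	6.98E-05	3.37	calibrator_not_detected
hsa-miR-149	7.43E-03	3.33	calibrator_not_detected
mmu-miR-187	1.92E-03	3.22	calibrator_not_detected
mmu-miR-433	7.82E-04	2.87	calibrator_not_detected
mmu-miR-34c	1.08E-04	2.81	calibrator_not_detected
mmu-miR-146b	2.44E-02	2.52	calibrator_not_detected
hsa-let-7e*	3.67E-07	2.27	calibrator_not_detected
mmu-miR-10a	2.49E-02	2.23	calibrator_not_detected
mmu-miR-134	2.06E-02	2.07	calibrator_not_detected
mmu-miR-494	1.42E-04	2.02	calibrator_not_detected
rno-miR-204*	5.97E-03	1.97	calibrator_not_detected
mmu-miR-383	3.11E-03	1.89	calibrator_not_detected
mmu-miR-487b	2.96E-03	1.87	calibrator_not_detected
mmu-miR-376a	4.14E-03	1.68	calibrator_not_detected
mmu-miR-137	2.01E-02	1.65	calibrator_not_detected
rno-miR-345-3p	5.67E-04	1.61	calibrator_not_detected
mmu-miR-381	3.45E-03	1.60	calibrator_not_detected
mmu-miR-455	3.32E-02	1.59	calibrator_not_detected
hsa-miR-99b*	1.94E-02	1.58	calibrator_not_detected
mmu-miR-125b*	3.70E-02	1.28	calibrator_not_detected
mmu-miR-345-3p	2.48E-02	1.17	calibrator_not_detected
mmu-miR-218-1*	4.93E-02	0.98	calibrator_not_detected
rno-miR-351	8.86E-03	0.86	calibrator_not_detected
mmu-miR-122	5.56E-05	1.41	valid
mmu-miR-667	9.46E-04	1.19	valid
mmu-miR-365	2.39E-03	0.93	valid
mmu-miR-34b-3p	6.71E-04	0.91	valid
mmu-miR-485-3p	3.61E-04	0.84	valid
mmu-miR-214	4.42E-07	0.80	valid
mmu-miR-204	1.71E-04	0.77	valid
hsa-miR-214	1.03E-05	0.75	valid
mmu-miR-193*	1.37E-03	0.74	valid
mmu-miR-384-5p	2.60E-02	0.74	valid
mmu-miR-125b-5p	2.47E-03	0.70	valid
mmu-miR-194	1.78E-03	0.69	valid
mmu-miR-127	1.59E-02	0.69	valid
mmu-miR-671-3p	1.94E-04	0.69	valid
mmu-miR-434-3p	1.61E-03	0.67	valid
mmu-miR-199a-3p	1.01E-04	0.62	valid
mmu-miR-132	6.76E-03	0.61	valid
mmu-miR-410	2.09E-02	0.60	valid
mmu-miR-872*	8.59E-03	0.58	valid
mmu-miR-192	3.06E-04	0.57	valid
mmu-miR-145	1.40E-03	0.56	valid
hsa-miR-671-5p	4.68E-03	0.53	valid
mmu-miR-574-3p	1.26E-03	0.53	valid
mmu-miR-532-5p	1.23E-02	0.52	valid
mmu-miR-337-5p	5.90E-03	0.52	valid
mmu-miR-375	4.70E-02	0.50	valid
mmu-miR-218	7.99E-04	0.50	valid
mmu-let-7a*	5.98E-03	0.49	valid
hsa-miR-455	2.99E-03	0.49	valid
mmu-miR-500	2.66E-03	0.46	valid
mmu-miR-1944	1.63E-02	0.45	valid
mmu-miR-685	1.30E-03	0.43	valid
mmu-miR-148a	1.47E-03	0.42	valid
mmu-miR-212	3.16E-02	0.41	valid
mmu-miR-224	6.52E-03	0.40	valid
mmu-miR-676	2.96E-03	0.40	valid
mmu-miR-152	9.64E-03	0.40	valid
mmu-miR-200a	4.06E-02	0.39	valid
hsa-miR-744*	1.19E-02	0.36	valid
mmu-miR-497	9.60E-03	0.35	valid
mmu-miR-532-3p	2.04E-02	0.30	valid
mmu-miR-133a	4.79E-02	0.27	valid
mmu-miR-19b	2.20E-02	-0.27	valid
mmu-miR-28	1.19E-02	-0.27	valid
mmu-miR-18a*	1.54E-02	-0.30	valid
mmu-miR-301a	2.62E-02	-0.32	valid
mmu-miR-18a	2.96E-02	-0.32	valid
mmu-miR-15b	7.79E-03	-0.34	valid
mmu-miR-879*	4.04E-02	-0.35	valid
mmu-miR-191	2.35E-03	-0.35	valid
mmu-let-7i	2.49E-02	-0.35	valid
mmu-miR-222	1.42E-02	-0.35	valid
mmu-let-7d	1.78E-02	-0.36	valid
hsa-miR-106b*	1.21E-02	-0.36	valid
mmu-miR-93	2.02E-02	-0.36	valid
mmu-miR-106a	2.31E-02	-0.37	valid
mmu-miR-16*	1.54E-02	-0.39	valid
mmu-miR-25	3.56E-02	-0.39	valid
mmu-miR-130b	2.38E-02	-0.40	valid
mmu-miR-2134	2.10E-02	-0.41	valid
mmu-miR-17	4.15E-03	-0.43	valid
mmu-miR-16	3.14E-02	-0.43	valid
mmu-miR-15a	2.51E-02	-0.44	valid
rno-miR-148b-5p	1.10E-02	-0.45	valid
mmu-miR-451	1.04E-02	-0.51	valid
mmu-miR-340-5p	1.11E-02	-0.53	valid
mmu-miR-20a	3.68E-03	-0.53	valid
hsa-miR-421	5.54E-04	-0.53	valid
mmu-miR-26b	1.48E-02	-0.57	valid
mmu-miR-1274a	2.25E-02	-0.60	valid
mmu-miR-186	3.50E-02	-0.60	valid
mmu-miR-142-3p	4.12E-03	-0.61	valid
mmu-miR-17*	4.59E-03	-0.62	valid
mmu-miR-301b	2.02E-03	-0.66	valid
mmu-miR-26a	1.46E-03	-0.66	valid
mmu-miR-186*	2.64E-03	-0.67	valid
mmu-miR-106b	1.92E-03	-0.68	valid
mmu-miR-31	1.59E-02	-0.86	valid
hsa-miR-875-5p	1.02E-02	-3.75	valid
rno-miR-196c	4.12E-02	-1.80	target_not_detected
mmu-miR-363	1.33E-02	-2.38	target_not_detected
mmu-miR-2138	4.71E-02	-2.52	target_not_detected
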