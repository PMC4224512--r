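mirna	p_value	log10_rq	ct_status
mmu-miR-15a*	1.8E-13	4.57	calibrator_not_detected
mmu-miR-495	1.5E-03	2.87	calibrator_not_detected
mmu-miR-673	3.0E-02	2.66	calibrator_not_detected
mmu-miR-433	9.8E-04	2.63	calibrator_not_detected
mmu-miR-146b	2.7E-02	2.48	calibrator_not_detected
mmu-miR-702	2.4E-02	2.24	calibrator_not_detected
mmu-miR-10a	2.6E-02	2.22	calibrator_not_detected
mmu-miR-700	2.4E-02	2.2	calibrator_not_detected
mmu-miR-134	1.9E-02	2.09	calibrator_not_detected
mmu-miR-487b	1.3E-03	2.01	calibrator_not_detected
mmu-miR-494	7.3E-05	1.96	calibrator_not_detected
hsa-miR-99b*	7.7E-03	1.87	calibrator_not_detected
mmu-miR-551b	2.1E-03	1.75	calibrator_not_detected
mmu-miR-376a	7.1E-04	1.72	calibrator_not_detected
rno-miR-551B	5.7E-03	1.62	calibrator_not_detected
mmu-miR-434-5p	2.9E-02	1.61	calibrator_not_detected
rno-miR-204*	1.7E-02	1.6	calibrator_not_detected
mmu-miR-467b	1.6E-02	1.6	calibrator_not_detected
mmu-miR-137	2.7E-02	1.54	calibrator_not_detected
rno-miR-345-3p	2.0E-03	1.41	calibrator_not_detected
mmu-miR-547	4.1E-02	1.3	calibrator_not_detected
mmu-miR-680	4.8E-02	1.14	calibrator_not_detected
mmu-miR-218-1*	3.0E-02	1.1	calibrator_not_detected
mmu-miR-345-3p	3.4E-02	1.09	calibrator_not_detected
mmu-miR-295	2.6E-02	1.09	calibrator_not_detected
rno-miR-351	6.3E-03	0.89	calibrator_not_detected
mmu-miR-122	2.2E-04	1.24	valid
mmu-miR-872	2.6E-02	0.98	valid
mmu-miR-667	7.9E-04	0.91	valid
mmu-miR-214	2.4E-07	0.88	valid
mmu-miR-485-3p	5.1E-04	0.83	valid
mmu-miR-365	9.5E-03	0.83	valid
mmu-miR-384-5p	9.8E-04	0.78	valid
mmu-miR-337-5p	1.0E-05	0.77	valid
mmu-miR-193*	7.4E-03	0.74	valid
mmu-miR-671-3p	2.1E-05	0.72	valid
hsa-miR-214	2.5E-05	0.71	valid
mmu-miR-574-3p	4.2E-05	0.71	valid
mmu-miR-192	3.5E-03	0.64	valid
mmu-miR-434-3p	7.2E-05	0.64	valid
mmu-miR-685	3.1E-04	0.63	valid
mmu-miR-193	3.5E-02	0.62	valid
mmu-miR-872*	2.8E-03	0.6	valid
mmu-let-7a*	4.4E-03	0.6	valid
mmu-miR-410	4.8E-03	0.58	valid
mmu-miR-125b-5p	1.6E-02	0.57	valid
mmu-miR-218	1.3E-03	0.54	valid
mmu-miR-34b-3p	2.5E-04	0.54	valid
mmu-miR-145	1.2E-03	0.53	valid
mmu-miR-500	8.2E-05	0.51	valid
mmu-miR-132	6.0E-03	0.48	valid
mmu-miR-127	3.3E-02	0.46	valid
mmu-miR-125a-5p	3.1E-03	0.46	valid
mmu-miR-199a-3p	1.4E-03	0.46	valid
mmu-miR-706	2.0E-02	0.44	valid
hsa-miR-671-5p	1.8E-02	0.44	valid
mmu-miR-152	2.4E-03	0.44	valid
mmu-miR-1944	4.0E-02	0.42	valid
mmu-miR-361	2.7E-02	0.38	valid
mmu-miR-376c	8.4E-03	0.37	valid
mmu-miR-362-3p	4.0E-02	0.37	valid
hsa-miR-744*	7.7E-03	0.36	valid
hsa-miR-455	3.0E-02	0.35	valid
mmu-miR-31*	2.4E-02	0.35	valid
mmu-miR-674*	4.3E-02	0.34	valid
mmu-miR-204	4.2E-03	0.32	valid
mmu-miR-212	2.4E-02	0.29	valid
mmu-miR-532-3p	2.9E-02	0.28	valid
mmu-miR-511	2.8E-02	0.26	valid
mmu-miR-1839-3p	4.9E-02	0.19	valid
mmu-miR-200c	4.7E-02	-0.22	valid
mmu-miR-484	2.7E-02	-0.23	valid
mmu-miR-18a*	1.6E-03	-0.25	valid
hsa-miR-425	4.7E-02	-0.26	valid
mmu-miR-1930	3.6E-02	-0.26	valid
mmu-miR-301a	4.2E-02	-0.26	valid
mmu-miR-2134	3.9E-03	-0.28	valid
mmu-miR-19b	1.3E-02	-0.29	valid
mmu-miR-222	4.6E-02	-0.31	valid
mmu-miR-141	3.9E-02	-0.33	valid
hsa-miR-200c	2.1E-03	-0.33	valid
mmu-miR-106a	2.0E-02	-0.34	valid
mmu-miR-130b	5.5E-03	-0.34	valid
mmu-miR-486	1.7E-02	-0.35	valid
mmu-miR-17	9.6E-03	-0.39	valid
mmu-miR-331-3p	1.3E-02	-0.41	valid
mmu-miR-652	7.1E-03	-0.41	valid
mmu-let-7d	7.6E-03	-0.41	valid
mmu-miR-17*	9.6E-03	-0.43	valid
mmu-miR-16	2.7E-02	-0.43	valid
hsa-miR-421	6.9E-04	-0.43	valid
mmu-miR-345-5p	2.4E-03	-0.43	valid
mmu-miR-18a	1.6E-03	-0.43	valid
mmu-miR-103	2.1E-02	-0.44	valid
mmu-miR-25	4.3E-03	-0.47	valid
mmu-miR-93	4.8E-03	-0.47	valid
mmu-miR-140	1.7E-02	-0.48	valid
mmu-let-7i	1.5E-03	-0.48	valid
mmu-miR-20a	8.0E-04	-0.48	valid
mmu-miR-20b	2.5E-02	-0.49	valid
mmu-miR-340-5p	2.0E-02	-0.5	valid
mmu-miR-186*	1.6E-02	-0.51	valid
mmu-miR-301b	7.0E-03	-0.54	valid
mmu-miR-15b	5.0E-04	-0.54	valid
mmu-miR-26a	4.1E-03	-0.57	valid
mmu-miR-142-3p	4.2E-03	-0.6	valid
mmu-miR-26b	7.4E-03	-0.63	valid
hsa-miR-106b*	5.9E-05	-0.64	valid
mmu-miR-451	5.0E-05	-0.78	valid
mmu-miR-106b	4.2E-05	-0.83	valid
mmu-miR-31	2.4E-02	-0.87	valid
hsa-miR-875-5p	2.5E-02	-3.16	valid
rno-miR-196c	2.2E-02	-1.39	target_not_detected
mmu-miR-463	2.2E-03	-1.75	target_not_detected
mmu-let-7e	3.7E-02	-1.98	target_not_detected
mmu-miR-363	4.4E-03	-2.95	target_not_detected
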