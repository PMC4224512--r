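mirna	IS1	IS2	IS3	IS4
mmu-miR-376a	1.99	1.70	1.72	1.68
hsa-miR-214	0.58	0.72	0.71	0.75
mmu-miR-214	0.54	0.64	0.88	0.80
mmu-miR-337-5p	0.52	0.49	0.77	0.52
mmu-miR-574-3p	0.51	0.53	0.71	0.53
mmu-miR-434-3p	0.41	0.61	0.64	0.67
mmu-miR-671-3p	0.39	0.37	0.72	0.69
mmu-miR-218	0.36	0.64	0.54	0.50
mmu-miR-199a-3p	0.32	0.42	0.46	0.62
hsa-miR-106b*	-0.40	-0.38	-0.64	-0.36
mmu-miR-106b	-0.47	-0.45	-0.83	-0.68
mmu-miR-31	-0.85	-1.03	-0.87	-0.86
rno-miR-196c	-1.81	-1.53	-1.39	-1.80
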