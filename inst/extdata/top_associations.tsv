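snp	trait	h0	hs	hd	hsd	p_S	p_D	maf	chrom
rs8014194	tc	0.16	0.005	0.07	0.77	0.06	1.9e-08	0.24	14
rs4420638	ldlc	0.30	0.36	0.005	0.34	6.3e-07	4.2e-03	0.19	19
rs646776	ldlc	0.04	0.92	0.005	0.04	3.7e-08	0.20	0.19	1
rs7633531	ldlc	0.13	0.84	0.005	0.03	1.4e-07	0.37	0.18	3
rs1260326	tg	0.005	0.83	0.005	0.17	5.0e-15	2.6e-02	0.45	2
rs964184	tg	0.005	0.99	0.005	0.03	1.9e-14	0.46	0.14	11
rs9644568	tg	0.06	0.90	0.005	0.04	4.5e-08	0.47	0.11	8
rs1883025	tg	0.35	0.63	0.005	0.02	6.4e-07	0.35	0.24	9
rs247616	hdlc	0.005	0.98	0.005	0.02	2.5e-32	0.45	0.32	16
rs4775041	hdlc	0.01	0.96	0.005	0.03	1.0e-08	0.86	0.25	15
rs1011685	hdlc	0.02	0.95	0.005	0.03	2.1e-08	0.58	0.12	8
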