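snp	chrom	pos	gene	trait	ea	oa	eaf	beta_stage1	se_stage1	p_stage1	beta_stage2	se_stage2	p_stage2	beta_combined	se_combined	p_combined	candidate	override
rs2860323	2	614210	TMEM18	pwv	G	A	0.12	0.09	0.02	5.9e-5	0.02	0.02	4.7e-1	0.06	0.02	3.9e-4	0	1
rs9436303	1	65430991	LEPR/LEPROT	bmi_ap	G	A	0.22	0.13	0.02	4.7e-8	0.05	0.01	6.7e-4	0.07	0.01	8.3e-9	0	0
rs10515235	5	96323352	PCSK1	bmi_ap	A	G	0.21	0.09	0.02	9.7e-7	0.03	0.01	1.5e-2	0.05	0.01	2.4e-6	1	0
rs1421085	16	53767042	FTO	age_ar	C	T	0.25	-0.10	0.02	6.1e-8	-0.13	0.01	7.1e-24	-0.12	0.01	3.1e-30	0	0
rs2956578	5	36497552	RANBP3L/SLC1A3	age_ar	G	A	0.31	0.11	0.02	6.7e-8	0.00	0.01	8.3e-1	0.04	0.01	1.1e-3	0	0
rs2817419	6	50845193	TFAP2B	age_ar	A	G	0.76	-0.10	0.02	2.9e-6	-0.07	0.01	1.8e-6	-0.08	0.01	4.4e-11	1	0
rs10938397	4	45180510	GNPDA2	bmi_ar	G	A	0.35	0.09	0.02	5.4e-6	0.05	0.01	3.1e-4	0.06	0.01	2.9e-8	1	0
rs2055816	11	85406487	DLG2	bmi_ar	C	T	0.25	-0.13	0.02	1.4e-7	-0.03	0.02	1.8e-1	-0.07	0.02	5.1e-6	1	0
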