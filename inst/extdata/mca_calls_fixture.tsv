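sample_id	chromosome	start	end	copy_type	clonal_fraction	lod_baf_phase	relative_coverage	expect_pass	expect_reasons
C01	1	1	5e+06	loss	0.2	30	1	TRUE	
C02	2	1	1900000	loss	0.2	30	1	FALSE	min_size
C03	3	1	2e+06	cnloh	0.2	30	1	TRUE	
C04	4	1	5e+06	loss	0.2	19	1	FALSE	lod_baf_phase
C05	5	1	5e+06	loss	0.2	20	1	TRUE	
C06	X	1	2e+07	cnloh	0.2	4.9	2	FALSE	lod_baf_phase
C07	X	1	2e+07	cnloh	0.2	5	2	TRUE	
C08	Y	1	1e+07	loss	0.2	4	1.5	FALSE	lod_baf_phase
C09	Y	1	1e+07	loss	0.2	6	1.5	TRUE	
C10	6	1	6e+06	gain	0.2	30	2.3	FALSE	constitutional_duplication
C11	6	1	6e+06	gain	0.2	30	2.25	TRUE	
C12	7	1	1e+07	gain	0.2	30	2.3	FALSE	constitutional_duplication
C13	7	1	10500000	gain	0.2	30	3	TRUE	
C14	8	1	4.9e+07	gain	0.2	30	3	TRUE	
C15	8	1	5e+07	gain	0.2	30	2.6	FALSE	constitutional_duplication
C16	1	1	2e+08	gain	0.2	30	2.6	FALSE	constitutional_duplication
C17	1	1	2e+08	gain	0.2	30	2.5	TRUE	
C18	2	1	6e+07	gain	0.2	30	2.4	TRUE	
C19	9	1	5e+06	loss	0.2	30	0.4	FALSE	deletion_coverage
C20	9	1	5e+06	loss	0.2	30	0.5	TRUE	
C21	10	1	1500000	loss	0.2	10	1	FALSE	min_size,lod_baf_phase
C22	11	1	5e+06	loss	0.2	15	0.3	FALSE	lod_baf_phase,deletion_coverage
C23	12	1	6e+06	gain	0.2	10	2.5	FALSE	lod_baf_phase,constitutional_duplication
C24	13	1	1e+06	loss	0.2	5	0.2	FALSE	min_size,lod_baf_phase,deletion_coverage
C25	X	1	1.2e+08	loss	0.2	10	1.3	TRUE	
C26	X	1	9.9e+07	loss	0.2	10	1.3	TRUE	
C27	14	1	8e+07	cnloh	0.2	25	1.8	TRUE	
C28	15	1	3e+07	gain	0.2	22	2.4	TRUE	
C29	16	1	2500000	gain	0.2	21	2.26	FALSE	constitutional_duplication
C30	17	1	2500000	gain	0.2	21	2.2	TRUE	
C31	18	1	5.5e+07	gain	0.2	30	2.51	FALSE	constitutional_duplication
C32	19	1	5.5e+07	gain	0.2	30	2.5	TRUE	
C33	20	1	3e+06	loss	0.2	19.99	1	FALSE	lod_baf_phase
C34	21	1	4e+07	loss	0.2	20.01	1	TRUE	
C35	22	1	2100000	loss	0.2	35	0.49	FALSE	deletion_coverage
C36	X	1	1.5e+08	loss	0.2	4	0.4	FALSE	lod_baf_phase,deletion_coverage
C37	3	1	9990000	gain	0.2	30	2.3	FALSE	constitutional_duplication
C38	4	1	5e+07	gain	0.2	30	2.5	TRUE	
C39	5	1	2e+06	gain	0.2	20	2.25	TRUE	
C40	6	1	1e+08	loss	0.2	28	0.6	TRUE	
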