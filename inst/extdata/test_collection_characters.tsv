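# Test-collection character table (38 wild-collected samples, transcribed).
# Tokens: its_result Yes / No / blank; its_closest names the species a
# failed ITS sequence was most similar to (blank when it met no reference);
# stem_class L / S / Sa (short with AAA apex) / s (lowercase variant token,
# normalised to SHORT); rbcl_label as printed. reported_id is the published
# final identification code (M/m/P/p/U) used for regression only.
sample_id	dna_no	nominal_species	its_result	its_closest	stem_class	rbcl_label	reported_id
mac 01	007	H. maculatum	No	H. maculatum	L	1	M
mac 02	011	H. maculatum	No	H. maculatum	L	1(p)	M
mac 03	012	H. maculatum	No	H. maculatum	L	1p	M
mac 04	018	H. maculatum	No	H. maculatum	L	1p	M
mac 05	030	H. maculatum			L	1p	m
mac 06	045	H. maculatum	No	H. maculatum	L	1-2	m
mac 07	001	H. maculatum			L	1	m
mac 08	031	H. maculatum	No	H. maculatum	L	1p	M
mac 09	027	H. maculatum	No	H. maculatum	L	1	M
mac 10	022	H. maculatum			L	1(p)	m
mac 11	014	H. maculatum			S	1p	p
mac 12	034	H. maculatum	No	H. maculatum	L	1p	M
mac 13	025	H. maculatum	No	H. maculatum	L	1p	M
mac 14	019	H. maculatum	No	H. maculatum	L	1	M
mac 15	036	H. maculatum	No	H. maculatum	s	1p	m
mac 16	023	H. maculatum	No	H. maculatum	L	1	M
perf 01	005	H. perforatum			S	1p	p
perf 02	043	H. perforatum	Yes		S	1-2	P
perf 03	017	H. perforatum	No		Sa	1	U
perf 04	026	H. perforatum	Yes		S	1p	P
perf 05	016	H. perforatum			S	1p	p
perf 06	038	H. perforatum			L	1p	U
perf 07	044	H. perforatum	Yes		S	1p	P
perf 08	035	H. perforatum	Yes		S	1	P
perf 09	029	H. perforatum	No		S	1p	U
perf 10	015	H. perforatum			S	1p	p
perf 11	032	H. perforatum	Yes		S	1	P
perf 12	041	H. perforatum			S	1p	p
perf 13	028	H. perforatum	No		Sa	1p	U
perf 14	024	H. perforatum			S	1p	p
perf 15	013	H. perforatum			L	1p	U
perf 16	037	H. perforatum	Yes		S	1p	P
perf 17	039	H. perforatum	Yes		S	1p	P
perf 18	020	H. perforatum	Yes		Sa	1p	P
perf 19	042	H. perforatum	Yes		Sa	1p	P
perf 20	040	H. perforatum	Yes		Sa	1p	P
perf 21	033	H. perforatum	Yes		S	1p	P
perf 22	021	H. perforatum			L	1(p)	U
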