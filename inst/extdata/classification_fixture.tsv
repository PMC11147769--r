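patient_id	sample_id	source	timepoint_years	chrom	pos	ref	alt	gene	protein_change	effect	vaf	alt_reads	depth	dbsnp	gnomad_af	expected_category	note
F01	F01_WB_t1	WB	0	chr2	25234373	C	T	DNMT3A	L100L	synonymous	0.05	100	2000	FALSE	NA	filtered	synonymous effect
F02	F02_WB_t1	WB	0	chr17	58734050	G	A	PPM1D	E525X	nonsynonymous	0.0045	9	2000	FALSE	NA	filtered	alt reads 9 below minimum 10
F03	F03_WB_t1	WB	0	chr17	58734051	G	A	PPM1D	E526X	nonsynonymous	0.005	10	2000	FALSE	NA	somatic	alt reads 10 inclusive boundary
F04	F04_WB_t1	WB	0	chr11	108236000	A	G	ATM	X1000	splice	0.03	60	2000	FALSE	NA	somatic	splice retained
F05	F05_WB_t1	WB	0	chr4	105234000	T	C	TET2	I200I	other	0.10	200	2000	FALSE	NA	filtered	non-coding effect
F06	F06_WB_t1	WB	0	chr4	105235000	C	G	TET2	Q810P	nonsynonymous	0.45	900	2000	FALSE	NA	somatic	VAF 45 percent not strictly above germline bound
F07	F07_WB_t1	WB	0	chr4	105236000	C	G	TET2	Q811P	nonsynonymous	0.451	902	2000	FALSE	NA	germline	VAF just above 45 percent
F08	F08_WB_t1	WB	0	chr1	11856378	G	A	GNB1	A50T	nonsynonymous	0.46	920	2000	TRUE	0.2	germline	germline rule precedes SNP exclusion
F09	F09_WB_t1	WB	0	chr2	25240000	G	A	DNMT3A	S770L	nonsynonymous	0.40	800	2000	TRUE	NA	somatic	VAF 40 percent not strictly above SNP bound
F10	F10_WB_t1	WB	0	chr2	25241000	G	A	DNMT3A	S771L	nonsynonymous	0.401	802	2000	TRUE	NA	snp_excluded	dbSNP flagged just above 40 percent
F11	F11_WB_t1	WB	0	chr20	31022000	C	T	ASXL1	G646W	nonsynonymous	0.401	802	2000	FALSE	0.02	snp_excluded	gnomAD AF above 1 percent
F12	F12_WB_t1	WB	0	chr20	31023000	C	T	ASXL1	G647W	nonsynonymous	0.401	802	2000	FALSE	0.01	somatic	gnomAD AF 1 percent not strictly above bound
F13	F13_WB_t1	WB	0	chr20	31024000	C	T	ASXL1	G648W	nonsynonymous	0.401	802	2000	FALSE	0.011	snp_excluded	gnomAD AF just above 1 percent
F14	F14_WB_t1	WB	0	chr2	25234374	C	T	DNMT3A	R882H	nonsynonymous	0.42	840	2000	TRUE	NA	somatic	hotspot overrides dbSNP exclusion
F15	F15_WB_t1	WB	0	chr9	5073770	G	T	JAK2	V617F	nonsynonymous	0.42	840	2000	FALSE	0.02	somatic	hotspot overrides gnomAD exclusion
F16	F16_WB_t1	WB	0	chr2	25234375	C	T	DNMT3A	R882C	nonsynonymous	0.46	920	2000	TRUE	0.2	germline	germline rule beats hotspot
F17	F17_WB_t1	WB	0	chr9	5073771	G	T	JAK2	V617F	nonsynonymous	0.0045	9	2000	FALSE	NA	filtered	hotspot never resurrects low read support
F18	F18_WB_t1	WB	0	chr17	76736877	C	T	SFRS2	P95H	nonsynonymous	0.41	820	2000	TRUE	NA	somatic	legacy symbol canonicalised then hotspot
F19	F19_WB_t1	WB	0	chr2	197402110	T	C	SF3B1	K700E	nonsynonymous	0.41	820	2000	FALSE	0.05	somatic	codon-level hotspot
F20	F20_WB_t1	WB	0	chr21	43104346	C	T	U2AF1	S34F	nonsynonymous	0.43	860	2000	TRUE	NA	somatic	codon-level hotspot
F21	F21_WB_t1	WB	0	chr21	43092956	T	C	U2AF1	Q157R	nonsynonymous	0.42	840	2000	TRUE	NA	somatic	codon-level hotspot
F22	F22_WB_t1	WB	0	chr2	197402635	G	T	SF3B1	K666N	nonsynonymous	0.41	820	2000	TRUE	NA	somatic	codon-level hotspot
F23	F23_WB_t1	WB	0	chr1	11856380	A	G	GNB1	K57E	nonsynonymous	0.41	820	2000	TRUE	NA	somatic	exact-change hotspot
F24	F24_WB_t1	WB	0	chr1	11856381	A	T	GNB1	K57N	nonsynonymous	0.41	820	2000	TRUE	NA	snp_excluded	GNB1 site requires the exact K57E change
F25	F25_WB_t1	WB	0	chr2	25242000	G	A	DNMT3A	R883H	nonsynonymous	0.41	820	2000	TRUE	NA	snp_excluded	adjacent codon is not a hotspot
F26	F26_WB_t1	WB	0	chr17	76736878	C	A	SRSF2	P95L	nonsynonymous	0.02	40	2000	FALSE	NA	somatic	ordinary low-VAF somatic call
F27	F27_WB_t1	WB	0	chr17	58740000	C	T	PPM1D	R552X	nonsynonymous	0.010	20	2000	FALSE	NA	somatic	CH-qualifying at 1 percent inclusive
F28	F28_WB_t1	WB	0	chr17	58741000	C	T	PPM1D	R553X	nonsynonymous	0.009	18	2000	FALSE	NA	somatic	below the 1 percent CH threshold
F29	F29_WB_t1	WB	0	chr17	43093000	G	A	BRCA1	E23X	stopgain	0.49	980	2000	FALSE	0.0001	germline	high-VAF truncating germline call
F30	F30_WB_t1	WB	0	chr4	105237000	CA	C	TET2	H900fs	truncating_indel	0.03	60	2000	FALSE	NA	somatic	protein-altering indel retained
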