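variant_id	gene	consequence	ac_case	an_case	ac_control	an_control	curated_class	evidence_tags	external_conflict	vus_temperature	true_or	true_label
var_00001	TRIOBP	splice_region	1	27690	0	13140	VUS	PM2_Supporting	FALSE	cold	1	benign
var_00002	OTOA	inframe_ins	3	27690	2	13140	VUS	PM2_Supporting	FALSE	cold	1	benign
var_00003	OTOA	inframe_ins	1	27690	0	13140	B	BA1	FALSE	NA	1	benign
var_00004	TRIOBP	frameshift	104	27690	60	13140	LB	BS1,BP4	FALSE	NA	1	benign
var_00005	USH2A	splice_acceptor	1	27690	0	13140	VUS	PM2_Supporting	FALSE	cold	1	benign
var_00006	LOXHD1	start_lost	57	27690	21	13140	LB	BS1,BP4	FALSE	NA	1	benign
var_00007	MYO7A	missense	22	27690	10	13140	B	BA1	FALSE	NA	1	benign
var_00008	LOXHD1	missense	491	27690	21	13140	LP	PM3_Strong,PM1,PM2_Supporting,PP3	FALSE	NA	12.8975	pathogenic
var_00009	COL11A2	frameshift	1	27690	1	13140	VUS	PM2_Supporting	FALSE	cold	1	benign
var_00010	OTOF	stop_lost	12	27690	7	13140	VUS	PM2_Supporting	FALSE	cold	1	benign
var_00011	TMC1	frameshift	1	27690	0	13140	LB	BS1,BP4	FALSE	NA	1	benign
var_00012	GJB2	splice_region	48	27690	20	13140	LB	BS1,BP4	FALSE	NA	1	benign
var_00013	USH2A	splice_region	1	27690	0	13140	VUS	PM2_Supporting	FALSE	cold	1	benign
var_00014	OTOF	inframe_del	1	27690	0	13140	LB	BS1,BP4	FALSE	NA	1	benign
var_00015	TMPRSS3	inframe_del	98	27690	51	13140	VUS	PM2_Supporting	FALSE	cold	1	benign
var_00016	LOXHD1	stop_lost	1	27690	0	13140	VUS	PM2_Supporting	FALSE	cold	1	benign
var_00017	OTOF	missense	2	27690	0	13140	VUS	PM2_Supporting,PP3	FALSE	cool	1	benign
var_00018	PTPRQ	inframe_ins	3	27690	0	13140	P	PVS1,PM3,PP3	FALSE	NA	4.0318	pathogenic
var_00019	OTOF	start_lost	1	27690	0	13140	VUS	PM2_Supporting	FALSE	cold	1	benign
var_00020	OTOF	inframe_del	231	27690	116	13140	VUS	PM2_Supporting	FALSE	cold	1	benign
var_00021	MYO7A	frameshift	2	27690	1	13140	VUS	PM2_Supporting,PP3	FALSE	cool	1	benign
var_00022	PCDH15	splice_region	772	27690	95	13140	LP	PM3_Strong,PM1,PM2_Supporting,PP3	FALSE	NA	4.3965	pathogenic
var_00023	OTOF	splice_acceptor	74	27690	34	13140	VUS	PM2_Supporting	FALSE	cold	1	benign
var_00024	TRIOBP	start_lost	3	27690	2	13140	VUS	PM2_Supporting,PP3	FALSE	cool	1	benign
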