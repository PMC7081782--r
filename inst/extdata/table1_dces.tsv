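gene_a	gene_b	scc_R_t1	scc_NR_t1	scc_R_t2	scc_NR_t2	scc_R_t3	scc_NR_t3	scc_R_t4	scc_NR_t4	scc_R_t5	scc_NR_t5	p_value
ADCY1	AKT1	-0.567	0.65	-0.717	0.7	-0.383	0.667	-0.883	0.283	-0.683	0.167	0.0001
FKBP10	HTR5A	0.633	-0.4	0.717	-0.433	0.833	-0.033	0.617	-0.217	0.967	-0.083	0.0087
DCAF13	KRR1	-0.533	0.467	-0.133	0.6	-0.6	0.35	0.533	-0.5	-0.7	0.217	0
ATRX	XRCC6	0.233	-0.533	0.283	-0.55	-0.75	-0.117	0.517	-0.467	0.567	-0.5	0.0095
CSF2	CXCR3	-0.1	-0.883	0.3	-0.7	-0.033	-0.783	0.283	-0.6	0.333	-0.767	0.0083
LIPE	PNLIP	0.033	0.783	0.533	-0.267	0.317	-0.567	0.8	0.1	0.433	-0.5	0.0059
EP300	GTF2H5	0.933	-0.3	0.633	-0.267	0.817	-0.733	0.617	-0.5	0.817	-0.017	0.0024
EP300	POLR2K	0.817	-0.35	0.783	-0.117	0.8	-0.733	0.65	-0.533	0.833	-0.167	0.0094
UBE2D2	UBXN7	0.467	-0.367	0.467	-0.267	0.633	-0.533	0.617	-0.033	0.717	-0.15	0.0068
ALMS1	CEP290	-0.683	0.25	-0.617	0.567	-0.717	-0.05	0.733	-0.617	0.783	-0.05	0.0047
RSRC1	SNU13	-0.683	0.433	-0.683	0.433	-0.45	0.333	-0.633	0.667	-0.217	0.717	0.0023
BCR	CUX1	0.217	-0.5	0.633	-0.767	0.533	-0.533	0.35	-0.65	0.333	-0.367	0.007
FGF21	FLT1	0.6	-0.433	0.717	-0.517	0.183	-0.667	0.983	-0.417	0.833	-0.117	0.0014
DYNC1H1	TUBGCP2	-0.7	0.3	-0.767	0.817	-0.767	0.317	-0.55	0.3	-0.467	0.517	0.0006
CXCL9	GRM4	0.1	-0.85	0.05	-0.583	0.25	-0.5	0.767	-0.083	0.8	-0.167	0.0007
DYNC1H1	PCNT	0.483	-0.75	0.4	-0.933	0.267	-0.65	0.567	-0.6	0.4	-0.367	0.004
CROCC	PCNT	-0.467	0.617	-0.283	0.817	-0.45	0.683	-0.517	0.733	-0.483	0.233	0.0079
IL2RA	IL2RB	-0.5	0.317	-0.583	0.017	-0.75	0.15	-0.783	0.517	-0.467	0.433	0.0072
MELK	RFC4	-0.367	0.683	-0.117	0.533	-0.633	0.617	-0.033	0.583	-0.867	0.133	0
HNRNPA2B1	RBM17	-0.733	0.233	-0.767	0.4	-0.617	0.2	-0.683	0.017	-0.9	-0.183	0.0026
ADCY3	NUDT2	0.6	-0.267	0.483	-0.65	0.417	-0.667	0.65	-0.433	0.25	-0.517	0.0095
AGA	GCA	0.817	-0.317	0.817	-0.133	0.8	-0.65	0.617	-0.617	0.633	-0.45	0.0099
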