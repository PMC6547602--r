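# Published per-subject CYP2D6 copy-number validation summary (15 CNV carriers
# detected among a 183-subject screened cohort): NGS normalized coverage ratio
# and z-score versus a 30-control two-copy reference panel, orthogonal TaqMan
# assay ratio and copy number, diplotype, duplicated allele (for >2-copy
# carriers; inferred from the reported genotypes), and reported phenotype.
subject	ratio	z	taqman_ratio	taqman_copy_number	genotype	duplicated_allele	phenotype_reported
PGAR844	0.55	-3.16	0.44	1	*1/*5	NA	IM
PGAR867	0.51	-3.36	0.44	1	*1/*5	NA	IM
PGON198	0.50	-2.96	0.53	1	*4/*5	NA	PM
PGST66	0.43	-3.54	0.45	1	*3/*5	NA	PM
PGST140	0.48	-3.39	0.43	1	*1/*5	NA	IM
PGST217	0.45	-3.55	0.45	1	*1/*5	NA	IM
PGST52	0.54	-2.74	0.45	1	*1/*5	NA	IM
PGAR1070	0.47	-3.33	0.48	1	*4/*5	NA	PM
PGAR1132	0.46	-3.79	0.49	1	*4/*5	NA	PM
PGAR1622	1.44	3.59	1.40	more_than_2	*1/*1	*1	UM
PGON142	1.30	3.20	1.48	more_than_2	*1/*1	*1	UM
PGON287	1.62	4.04	1.90	more_than_2	*41/*4	*4	IM
PGST38	1.32	1.91	1.38	more_than_2	*1/*4	*4	IM
PGON194	1.29	2.25	1.98	more_than_2	*1/*4	*4	IM
PGST223	1.60	3.25	1.86	more_than_2	*1/*1	*1	UM
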