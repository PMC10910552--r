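id	cdna_hgvs	protein_hgvs	mutation_type	inheritance	disease	allele_count	n_patients	has_segregation	has_clinical_characterization	af_gnomad	af_jpn	af_genomeasia	af_gme
V001	c.967G>A	p.Asp323Asn	missense	recessive	AR_bestrophinopathy	2	2	true	true	0.00001	.	.	.
V002	c.970G>T	p.Glu324Ter	nonsense	recessive	AR_bestrophinopathy	2	1	true	true	.	.	.	.
V003	c.1740-1G>C	.	splicing	recessive	AR_bestrophinopathy	2	2	true	true	.	.	.	.
V004	c.1622del	p.Leu541fs	frameshift	recessive	AR_bestrophinopathy	2	1	false	true	.	.	.	.
V005	c.74G>A	p.Arg25Gln	missense	dominant	BVMD	6	5	true	true	0.00002	.	.	.
V006	c.653G>A	p.Arg218His	missense	dominant	BVMD	4	3	true	true	.	.	.	.
V007	c.887A>G	p.Asn296Ser	missense	dominant	BVMD	5	4	true	true	.	.	.	.
V008	c.1000A>G	p.Thr334Ala	missense	dominant	BVMD	3	2	true	true	0.012	.	.	.
V009	c.500T>C	p.Leu167Pro	missense	recessive	AR_bestrophinopathy	1	1	false	false	.	.	.	.
V010	c.300G>A	p.Leu100=	silent	unknown	other	1	1	true	true	.	.	.	.
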