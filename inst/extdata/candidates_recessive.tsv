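Gene	Chr	Pos	Ref	Alt	cDNA	Protein	ExonicClass	CADD	REVEL	SIFT	PolyPhen2	MutationTaster	Model
CPT2	1	.	T	G	NM_000098:c.T1055G	p.F352C	nonsynonymous_SNV	22.1	0.521	D (0)	D (0.999)	P (0)	autosomal_recessive
LRP2	2	.	A	C	NM_004525:c.A12628C	p.I4210L	nonsynonymous_SNV	21.8	0.503	D (0)	D (0.995)	P (0)	autosomal_recessive
ERCC6L2	9	.	T	C	NM_001010895:c.T1742C	p.V581A	nonsynonymous_SNV	20.5	0.512	D (0.001)	.	P (0)	autosomal_recessive
NXPE1	11	.	G	A	NM_152315:c.G631A	p.G211R	nonsynonymous_SNV	20.2	0.501	D (0)	D (1.0)	P (0.002)	autosomal_recessive
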