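patient	gene	transcript	nucleotide_change	amino_acid_change	variant_type	inheritance	acmg_classification	described_before
1	VAMP2	NM_014232.2	c.128_130delTGG	p.Val43del	In-frame	De novo	Pathogenic	Yes
2	SYNGAP1	NM_006772.2	c.1861C>T	p.Arg621*	Nonsense	De novo	Pathogenic	No
3	TBL1XR1	NM_024665.5	c.1000T>C	p.Cys334Arg	Missense	De novo	Likely pathogenic	No
4	TBL1XR1	NM_024665.5	c.1043A>G	p.His348Arg	Missense	De novo	Likely pathogenic	No
5	SATB2	NM_001172509.1	c.1826delA	p.Asp609Alafs*15	Frameshift	De novo	Pathogenic	No
6	KCNQ3	NM_004519.3	c.688C>T	p.Arg230Cys	Missense	De novo	Pathogenic	Yes
7	SMARCE1	NM_003079.4	c.237+1G>T	p.Ala53_Lys79del	Splice site	De novo	Likely pathogenic	Yes
8	SPTAN1	NM_001130438.2	c.6592_6597dupCTGCAG	p.Leu2198_Gln2199dup	In-frame	De novo	Likely pathogenic	No
9	ASXL3	NM_030632.2	c.3106C>T	p.Arg1036*	Nonsense	De novo	Pathogenic	Yes
10	LAS1L	NM_031206.4	c.1237G>A	p.Gly413Arg	Missense	X-linked	Likely pathogenic	No
14	SLC6A1	NM_003042.3	c.889G>A	p.Gly297Arg	Missense	De novo	Pathogenic	Yes
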