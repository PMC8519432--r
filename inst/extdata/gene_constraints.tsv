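gene	transcript_id	lof_intolerant	known_pathogenic_changes	source_note
VAMP2	NM_014232.2	FALSE	p.Val43del	identical in-frame deletion previously reported pathogenic
SYNGAP1	NM_006772.2	TRUE		LoF-intolerant; null alleles established mechanism
TBL1XR1	NM_024665.5	FALSE
SATB2	NM_001172509.1	TRUE		LoF-intolerant; haploinsufficiency established
KCNQ3	NM_004519.3	FALSE	p.Arg230Cys	identical substitution previously established pathogenic
SMARCE1	NM_003079.4	FALSE	p.Ala53_Lys79del	splice effect predicts in-frame exon skip (not a null allele)
SPTAN1	NM_001130438.2	FALSE
ASXL3	NM_030632.2	TRUE	p.Arg1036*	identical nonsense previously reported
LAS1L	NM_031206.4	FALSE
SLC6A1	NM_003042.3	FALSE	p.Gly297Arg	identical substitution previously reported
HSF2	NM_004506.3	TRUE		LoF-intolerant candidate gene
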