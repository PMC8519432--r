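##gff-version 3
##source-version rtracklayer 1.62.0
##date 2026-09-30
chr1	rtracklayer	CDS	5000	5350	.	+	.	ID=NM_014232.2.cds1;transcript_id=NM_014232.2;gene_name=VAMP2
chr2	rtracklayer	CDS	5000	6919	.	+	.	ID=NM_006772.2.cds1;transcript_id=NM_006772.2;gene_name=SYNGAP1
chr3	rtracklayer	CDS	5000	6544	.	+	.	ID=NM_024665.5.cds1;transcript_id=NM_024665.5;gene_name=TBL1XR1
chr4	rtracklayer	CDS	5000	6919	.	+	.	ID=NM_001172509.1.cds1;transcript_id=NM_001172509.1;gene_name=SATB2
chr5	rtracklayer	CDS	5000	6319	.	-	.	ID=NM_004519.3.cds1;transcript_id=NM_004519.3;gene_name=KCNQ3
chr6	rtracklayer	CDS	5000	5155	.	+	.	ID=NM_003079.4.cds1;transcript_id=NM_003079.4;gene_name=SMARCE1
chr6	rtracklayer	CDS	5656	5736	.	+	.	ID=NM_003079.4.cds2;transcript_id=NM_003079.4;gene_name=SMARCE1
chr6	rtracklayer	CDS	6237	6749	.	+	.	ID=NM_003079.4.cds3;transcript_id=NM_003079.4;gene_name=SMARCE1
chr7	rtracklayer	CDS	5000	11629	.	+	.	ID=NM_001130438.2.cds1;transcript_id=NM_001130438.2;gene_name=SPTAN1
chr8	rtracklayer	CDS	5000	8134	.	+	.	ID=NM_030632.2.cds1;transcript_id=NM_030632.2;gene_name=ASXL3
chrX	rtracklayer	CDS	5000	6259	.	+	.	ID=NM_031206.4.cds1;transcript_id=NM_031206.4;gene_name=LAS1L
chr9	rtracklayer	CDS	5000	5929	.	+	.	ID=NM_003042.3.cds1;transcript_id=NM_003042.3;gene_name=SLC6A1
chr10	rtracklayer	CDS	5000	5599	.	+	.	ID=NM_004506.3.cds1;transcript_id=NM_004506.3;gene_name=HSF2
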