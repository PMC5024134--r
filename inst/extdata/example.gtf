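chr1	lncdev	exon	101	200	.	+	.	gene_id "g1"; transcript_id "t1"; biotype "coding";
chr1	lncdev	exon	301	450	.	+	.	gene_id "g1"; transcript_id "t1"; biotype "coding";
chr1	lncdev	exon	101	450	.	+	.	gene_id "g1"; transcript_id "t2"; biotype "coding";
chr2	lncdev	exon	5001	5200	.	-	.	gene_id "g2"; transcript_id "t3"; biotype "lncRNA";
chr2	lncdev	exon	5601	5900	.	-	.	gene_id "g2"; transcript_id "t3"; biotype "lncRNA";
chr2	lncdev	exon	6201	6350	.	-	.	gene_id "g2"; transcript_id "t3"; biotype "lncRNA";
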