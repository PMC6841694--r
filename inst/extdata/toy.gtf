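##description: synthetic toy annotation (three genes on one contig)
chrT	toy	gene	101	400	.	+	.	gene_id "GA"; gene_name "GA"; gene_type "protein_coding";
chrT	toy	transcript	101	400	.	+	.	gene_id "GA"; transcript_id "GA.T1"; gene_name "GA"; gene_type "protein_coding";
chrT	toy	exon	101	200	.	+	.	gene_id "GA"; transcript_id "GA.T1"; gene_name "GA"; gene_type "protein_coding";
chrT	toy	exon	301	400	.	+	.	gene_id "GA"; transcript_id "GA.T1"; gene_name "GA"; gene_type "protein_coding";
chrT	toy	gene	151	250	.	-	.	gene_id "GB"; gene_name "GB"; gene_type "lncRNA";
chrT	toy	transcript	151	250	.	-	.	gene_id "GB"; transcript_id "GB.T1"; gene_name "GB"; gene_type "lncRNA";
chrT	toy	exon	151	250	.	-	.	gene_id "GB"; transcript_id "GB.T1"; gene_name "GB"; gene_type "lncRNA";
chrT	toy	gene	5001	5300	.	+	.	gene_id "GC"; gene_name "GC"; gene_type "protein_coding";
chrT	toy	transcript	5001	5300	.	+	.	gene_id "GC"; transcript_id "GC.T1"; gene_name "GC"; gene_type "protein_coding";
chrT	toy	exon	5001	5300	.	+	.	gene_id "GC"; transcript_id "GC.T1"; gene_name "GC"; gene_type "protein_coding";
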