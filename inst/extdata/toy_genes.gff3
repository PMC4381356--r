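##gff-version 3
chr1	toy	gene	1	300	.	+	.	ID=GeneA
chr1	toy	mRNA	1	300	.	+	.	ID=GeneA.1;Parent=GeneA
chr1	toy	exon	1	100	.	+	.	Parent=GeneA.1
chr1	toy	exon	201	300	.	+	.	Parent=GeneA.1
chr1	toy	mRNA	1	300	.	+	.	ID=GeneA.2;Parent=GeneA
chr1	toy	exon	1	100	.	+	.	Parent=GeneA.2
chr1	toy	exon	151	300	.	+	.	Parent=GeneA.2
chr1	toy	gene	1001	1400	.	+	.	ID=GeneB
chr1	toy	mRNA	1001	1400	.	+	.	ID=GeneB.1;Parent=GeneB
chr1	toy	exon	1001	1100	.	+	.	Parent=GeneB.1
chr1	toy	exon	1201	1250	.	+	.	Parent=GeneB.1
chr1	toy	exon	1301	1400	.	+	.	Parent=GeneB.1
chr1	toy	mRNA	1001	1400	.	+	.	ID=GeneB.2;Parent=GeneB
chr1	toy	exon	1001	1100	.	+	.	Parent=GeneB.2
chr1	toy	exon	1301	1400	.	+	.	Parent=GeneB.2
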