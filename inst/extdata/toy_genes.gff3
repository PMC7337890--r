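##gff-version 3
##sequence-region chr1 1 50000
##sequence-region chr2 1 30000
chr1	toy	gene	1000	3000	.	+	.	ID=geneA;biotype=protein_coding
chr1	toy	five_prime_UTR	1000	1200	.	+	.	Parent=geneA
chr1	toy	CDS	1201	1800	.	+	0	Parent=geneA
chr1	toy	CDS	2000	2600	.	+	0	Parent=geneA
chr1	toy	three_prime_UTR	2601	3000	.	+	.	Parent=geneA
chr1	toy	gene	10000	14000	.	-	.	ID=geneB;biotype=protein_coding
chr1	toy	mRNA	10000	14000	.	-	.	ID=geneB.t1;Parent=geneB
chr1	toy	five_prime_UTR	13500	14000	.	-	.	Parent=geneB.t1
chr1	toy	CDS	11000	13499	.	-	0	Parent=geneB.t1
chr1	toy	three_prime_UTR	10000	10999	.	-	.	Parent=geneB.t1
chr2	toy	gene	5000	5080	.	+	.	ID=geneC;biotype=tRNA
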