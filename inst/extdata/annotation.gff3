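##gff-version 3
# synthetic demo annotation, seed 4242
I	demo	gene	551	1450	.	+	.	ID=SPBC11B10.09;Name=cdc2;synonyms=cdk1
I	demo	mRNA	551	1450	.	+	.	ID=SPBC11B10.09.1;Parent=SPBC11B10.09
I	demo	CDS	601	900	.	+	0	ID=SPBC11B10.09.1:cds1;Parent=SPBC11B10.09.1
I	demo	CDS	1001	1400	.	+	0	ID=SPBC11B10.09.1:cds2;Parent=SPBC11B10.09.1
II	demo	gene	901	1500	.	-	.	ID=SPNCRNA.01;Name=SPNCRNA.01
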