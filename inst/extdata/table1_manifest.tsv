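accession	tissue	platform	group	n
GSE1919	synovial	Affymetrix HGU95A	OA	5
GSE1919	synovial	Affymetrix HGU95A	NT	5
GSE1919	synovial	Affymetrix HGU95A	RA	5
GSE2053	synovial	HUMAN UNIGENE SetI Part 1	NT	4
GSE2053	synovial	HUMAN UNIGENE SetI Part 1	RA	4
GSE3698	synovial	Human Unigene3.1 cDNA Array 37.5K v1.0	RA	18
GSE3698	synovial	Human Unigene3.1 cDNA Array 37.5K v1.0	OA	19
GSE7669	synovial	Affymetrix HGU95 2.0	RA	6
GSE7669	synovial	Affymetrix HGU95 2.0	OA	6
GSE9027	synovial		RA	28
GSE12021	synovial	Affymetrix HGU133A HGU133B Array	OA	20
GSE12021	synovial	Affymetrix HGU133A HGU133B Array	RA	22
GSE12021	synovial	Affymetrix HGU133A HGU133B Array	NT	13
GSE17755	peripheral_blood	Hitachisoft AceGene Human OligoChip 30K 1 Chip Version	RA	112
GSE17755	peripheral_blood	Hitachisoft AceGene Human OligoChip 30K 1 Chip Version	NT	8
GSE17755	peripheral_blood	Hitachisoft AceGene Human OligoChip 30K 1 Chip Version	NT	45
GSE27390	bone_marrow	Affymetrix HGU133 Plus 2.0	RA	9
GSE27390	bone_marrow	Affymetrix HGU133 Plus 2.0	OA	11
GSE29746	synovial	Whole Human Genome Microarray 4x44K G4112F	RA	9
GSE29746	synovial	Whole Human Genome Microarray 4x44K G4112F	OA	11
GSE36700	synovial	Affymetrix HGU133 Plus 2.0	OA	6
GSE36700	synovial	Affymetrix HGU133 Plus 2.0	RA	7
GSE39340	synovial	Illumina HumanHT-12 V4.0 expression beadchip	RA	10
GSE39340	synovial	Illumina HumanHT-12 V4.0 expression beadchip	OA	7
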