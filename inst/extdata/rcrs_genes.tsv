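# rCRS gene coordinates (1-based inclusive); the control region
# spans the origin of the circular molecule (16024-16569 + 1-576).
gene	start	end	strand	type
RNR1	648	1601	+	rRNA
RNR2	1671	3229	+	rRNA
ND1	3307	4262	+	protein
ND2	4470	5511	+	protein
CO1	5904	7445	+	protein
CO2	7586	8269	+	protein
ATP8	8366	8572	+	protein
ATP6	8527	9207	+	protein
CO3	9207	9990	+	protein
ND3	10059	10404	+	protein
ND4L	10470	10766	+	protein
ND4	10760	12137	+	protein
ND5	12337	14148	+	protein
ND6	14149	14673	-	protein
CYTB	14747	15887	+	protein
CR_a	16024	16569	+	control
CR_b	1	576	+	control
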