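analyte	gene	chrom	tss
CRP	CRP	1	159712289
C3	C3	19	6720662
C3a	C3	19	6720662
C5a	C5	9	123714615
Bb	CFB	6	31913721
FactorB	CFB	6	31913721
FactorD	CFD	19	859665
FactorH	CFH	1	196651754
SC5b9	C9	5	39284145
BbC3ratio	CFB	6	31913721
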