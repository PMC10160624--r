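gene	motif	normal_count	threshold
AR	CAG	22	35
ATN1	CAG	16	36
HTT	CAG	17	36
ATXN7	CAG	10	27
ATXN1	CAG	29	36
ATXN3	CAG	24	27
C9ORF72	GGGGCC	5	25
FXN	GAA	9	60
DMPK	CTG	21	36
FMR1	CGG	30	45
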