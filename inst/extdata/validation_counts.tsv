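# Analytical-validation confusion counts per variant class
# (GIAB-derived truth-set confirmation experiment; printed study inputs)
variant_class	tp	fp	fn	tn
snv	164	0	1	168
small_indel	137	0	3	168
sv	118	0	6	168
mito	70	1	0	34
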