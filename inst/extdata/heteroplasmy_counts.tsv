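# Observed mitochondrial allele counts (alt reads / total depth) from the
# clinical heteroplasmy concordance experiment; printed study inputs.
# expected_percent = heteroplasmy level known for the sample.
variant	alt_count	depth	expected_percent
m.9518C>T	20	1274	1
m.13376T>C	34	1280	2
m.15737G>A	41	1284	2
m.6210T>C	82	1201	7
m.8344A>G	658	1699	35
m.3460G>A	1835	1905	95
m.1438A>G	1146	1193	100
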