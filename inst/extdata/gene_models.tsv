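gene_id	locus	strand
GWD1	chr05:9901255.9916669	+
DMR6-1	chr03:46,329605.46336003	-
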