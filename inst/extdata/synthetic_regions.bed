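chr1	200	450	toy_long_range_ld_1
chr2	0	100	toy_long_range_ld_2
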