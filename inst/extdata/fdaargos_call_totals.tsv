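type	total_calls	fp_calls
SNP	26529429	1545957
INDEL	463386	246852
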