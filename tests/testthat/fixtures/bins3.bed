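chr2L	0	10000
chr2L	10000	20000
chr2L	20000	30000
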