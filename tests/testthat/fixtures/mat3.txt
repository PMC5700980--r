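10 4 1
4 8 2
1 2 6
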