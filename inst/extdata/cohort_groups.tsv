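group	n_pairs
control	11
25nM	13
50nM	23
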