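group,n_AA,n_AG,n_GG
case,21,54,31
control,92,115,50
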