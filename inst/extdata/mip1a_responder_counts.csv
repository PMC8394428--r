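genotype,responder,non_responder
AA,6,1
AG,4,3
GG,1,6
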