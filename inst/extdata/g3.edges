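c l1
c l2
c l3
c l4
c l5
c l6
c l7
c l8
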