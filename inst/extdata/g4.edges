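s1 h
s2 h
s3 h
s4 h
s5 h
s6 h
s7 h
h t
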