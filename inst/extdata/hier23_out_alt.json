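{"direction":"out","coefficients":[6,10,5,0,0,0,0,1,1]}
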