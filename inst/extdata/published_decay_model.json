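{"span":0.7235,"rate_k":0.2883,"plateau":0.2683,"r_squared":0.716}
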