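distinctiveness,identified_adults
D1,36
D2,51
D3,4
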