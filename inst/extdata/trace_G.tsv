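G(Low)
G(Low)
G(Mid)
G(Mid)
G(Mid)
G(High)
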