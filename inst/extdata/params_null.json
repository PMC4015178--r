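{"pi": [0.1, 0.2, 0.3, 0.4], "s": [0.2, 0.25, 0.2, 0.2, 0.15, 0.2]}
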