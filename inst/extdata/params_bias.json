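{"pi": [0.2, 0.3, 0.2, 0.3], "s": [0.2, 0.1, 0.3, 0.3, 1.0, 0.2]}
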