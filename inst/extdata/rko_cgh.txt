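rev ish enh(7q21qter, 8q11qter, 9q22qter, 12pterq14, 16q22qter, 20, 22), amp(8q22qter, 9q34qter)
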