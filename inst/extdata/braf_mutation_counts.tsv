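group	positive	tested	not_available
sporadic-MSI	17	33	7
sporadic-MSS	0	40	3
Lynch	0	15	12
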