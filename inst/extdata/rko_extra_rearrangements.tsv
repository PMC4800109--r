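token	recurrence
del(X)	2
del(6p)	2
der(12)t(5;12)	2
der(10)t(2;10)(p21;q11)	2
der(20)t(2;20)	2
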