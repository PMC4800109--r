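karyotype	n_metaphases	total_metaphases
47 (44~49), XX, del(2)(p21), der(3)t(3;5), del(5q), dup(7)(q21q36), +der(8)t(8;8)(p12;q21), del(9), +der(12)t(2;12), +der(20)t(9;20)(q22;p13), and der(22)t(16;22)	14	20
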