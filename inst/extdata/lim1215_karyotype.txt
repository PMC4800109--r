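# LIM1215: stable karyotype
46 (45–47), XY, del(3p), der(13)t(1;13)
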