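index	class	min	max	mean
aneuploid_index	MSI	1	8	3.1
aneuploid_index	MSS	8	19	14.2
centromere_variability	MSI	1	3	2
centromere_variability	MSS	6	30	15.4
n_rearranged	MSI	0	5	2.7
n_rearranged	MSS	9	24	15.8
n_cgh_changes	MSI	0	4	2.4
n_cgh_changes	MSS	11	30	19.4
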