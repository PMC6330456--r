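pair	n_wggs	n_csgs	printed_pcsgs
dog	24580	294	1.20
silkworm	15665	421	2.69
chicken	17858	148	0.83
rice	91080	6892	7.57
soybean_landrace	54174	3614	6.67
soybean_improved	54174	2987	5.51
cotton_whole	70478	1777	2.52
cotton_At	32032	549	1.71
cotton_Dt	34402	1228	3.57
maize_ear	39621	1606	4.05
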