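chromosome	length_cM
chr1	286.28
chr2	268.84
chr3	223.36
chr4	214.55
chr5	204.09
chr6	192.04
chr7	187.22
chr8	168.00
chr9	166.36
chr10	181.14
chr11	158.22
chr12	174.68
chr13	125.71
chr14	120.20
chr15	141.86
chr16	134.04
chr17	128.49
chr18	117.71
chr19	107.73
chr20	108.27
chr21	62.79
chr22	74.11
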