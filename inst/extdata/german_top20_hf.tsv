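# Published top-20 five-locus (HLA-A~B~C~DRB1~DQB1) haplotype frequencies,
# German donor population (estimation sample n = 370,856); percent scale.
# 'g'-group suffixes are carried verbatim as part of the allele token.
haplotype	frequency
01:01g~08:01g~07:01g~03:01~02:01g	6.06
03:01g~07:02g~07:02g~15:01~06:02	3.31
02:01g~07:02g~07:02g~15:01~06:02	1.94
03:01g~35:01g~04:01g~01:01~05:01	1.58
02:01g~15:01g~03:04g~04:01~03:02g	1.24
02:01g~44:02g~05:01g~04:01~03:01g	1.06
29:02g~44:03~16:01~07:01~02:01g	1.03
02:01g~40:01g~03:04g~13:02~06:04g	1.02
02:01g~13:02g~06:02g~07:01~02:01g	0.84
01:01g~57:01g~06:02g~07:01~03:03g	0.81
23:01g~44:03g~04:01g~07:01~02:01g	0.74
02:01g~57:01g~06:02g~07:01~03:03g	0.73
24:02g~07:02g~07:02g~15:01~06:02	0.72
30:01g~13:02g~06:02g~07:01~02:01g	0.71
02:01g~15:01g~03:03g~13:01g~06:03g	0.66
11:01g~35:01g~04:01g~01:01~05:01	0.59
02:01g~08:01g~07:01g~03:01~02:01g	0.58
25:01g~18:01g~12:03g~15:01~06:02	0.55
01:01g~07:02g~07:02g~15:01~06:02	0.50
02:01g~44:02g~05:01g~13:01g~06:03g	0.44
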