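"order","len_mean","len_sd","rad_mean","rad_sd","delta_n"
1,0.7766,0.1165,0.0867,0.013,1
2,0.8854,0.1328,0.098,0.0147,1
3,1.0093,0.1514,0.1107,0.0166,1
4,1.1506,0.1726,0.1251,0.0188,1
5,1.3117,0.1968,0.1414,0.0212,1
6,1.4954,0.2243,0.1598,0.024,1
7,1.7047,0.2557,0.1806,0.0271,1
8,1.9434,0.2915,0.204,0.0306,1
9,2.2154,0.3323,0.2306,0.0346,1
10,2.5256,0.3788,0.2605,0.0391,1
11,2.8792,0.4319,0.2944,0.0442,1
12,3.2823,0.2626,0.3327,0.0266,1
13,3.7418,0.2993,0.3759,0.0301,2
14,4.2657,0.3413,0.4248,0.034,2
15,4.8628,0.389,0.48,0.0384,2
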