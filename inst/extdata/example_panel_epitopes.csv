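clone_id,kd_nM,ag_blocking,ag_non_blocking,ag_ab1_complex
14F9,0.004,No,Yes,Yes
14B11,0.028,No,Yes,Yes
3E3,0.079,No,Yes,Yes
21E2,0.083,No,Yes,Yes
15A9,0.126,No,Yes,Yes
2ID7,0.021,No,Yes,No
1F9,0.023,No,Yes,No
21A6,0.031,No,Yes,No
23C7,0.055,No,Yes,No
24B4,0.072,No,Yes,No
9H10,0.073,No,Yes,No
19C4,0.088,No,Yes,No
23D4,0.098,No,Yes,No
15A12,0.101,No,Yes,No
28A4,0.108,No,Yes,No
21F7,0.129,No,Yes,No
20F6,0.131,No,Yes,No
15C11,0.252,No,Yes,No
27B5,0.366,No,Yes,No
18C9,0.167,Yes,No,No
28D6,0.432,Yes,No,No
12A8,0.351,Yes,No,No
19B2,5.688,Yes,No,No
19F6,4.517,Yes,No,No
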