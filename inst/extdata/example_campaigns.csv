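project,lc_germline,lc_control,lc_identity_pct,hc_germline,hc_control,hc_identity_pct,control_label,specific_clones,cloned,uniqueness_pct,kd_range_nM
A,hIGKV1-39,K1,98,hIGHV1-46,H1,98,K1H1,146,96,78,0.002-71
B,hIGKV4-01,K4,99,hIGHV1-46,H1,99,K4H1,75,75,59,0.04-8
C,hIGKV1-16,K1,99,hIGHV4-59,H4,93,K1H4,901,48,88,0.01-44
D,hIGKV4-01,K4,99,hIGHV1-03,H1,99,K4H1,48,48,55,0.003-4
E,hIGKV1-16,K1,100,hIGHV3-23,H3,98,K1H3,34,34,71,0.004-6
F,hIGKV1-05,K1,93,hIGHV1-02,H1,89,K1H1,48,48,83,0.03-202
G,hIGKV1-16,K1,96,hIGHV3-48,H3,99,K1H3,37,37,76,0.15-4
H,hIGKV1-12,K1,93,hIGHV1-46,H1,98,K1H1,796,48,92,0.016-1
I,hIGKV1-39,K1,98,hIGHV1-46,H1,99,K1H1,79,42,69,0.007-167
J,hIGKV1-12,K1,100,hIGHV3-23,H3,96,K1H3,659,48,81,0.001-2
K,hIGKV2-28,K2,98,hIGHV3-23,H3,96,K2H3,967,96,75,0.006-8
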