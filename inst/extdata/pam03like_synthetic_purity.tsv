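sample	purity
LiM 1	0.35
LiM 2	0.42
LiM 3	0.48
LiM 4	0.45
LiM 5	0.3
LuM 1	0.21
LuM 2	0.24
LuM 3	0.27
PT 10	0.4
PT 11	0.38
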