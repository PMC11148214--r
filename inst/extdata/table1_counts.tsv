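group	variable	level	n
gdm	education	primary-or-below	305
gdm	education	middle	262
gdm	education	high	521
gdm	education	college-or-above	580
gdm	gravidity	1	684
gdm	gravidity	>=2	984
gdm	parity	0	1060
gdm	parity	>=1	608
gdm	smoking	no	1637
gdm	smoking	yes	22
gdm	smoking	unknown	9
gdm	alcohol	no	1639
gdm	alcohol	yes	17
gdm	alcohol	unknown	12
non_gdm	education	primary-or-below	1243
non_gdm	education	middle	1138
non_gdm	education	high	2303
non_gdm	education	college-or-above	2796
non_gdm	gravidity	1	3373
non_gdm	gravidity	>=2	4107
non_gdm	parity	0	5185
non_gdm	parity	>=1	2295
non_gdm	smoking	no	7352
non_gdm	smoking	yes	82
non_gdm	smoking	unknown	46
non_gdm	alcohol	no	7325
non_gdm	alcohol	yes	104
non_gdm	alcohol	unknown	51
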