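mutation	residue_id	side	buried	charged	hbond_partners	salt_bridges	cavity_volume
R683W	683	wt	TRUE	TRUE	P670;D621;Q619	D621:3.1	612.300
R683W	683	mut	TRUE	FALSE	.	.	521.796
M575T	575	wt	TRUE	FALSE	.	.	540.000
M575T	575	mut	TRUE	FALSE	.	.	464.100
R639I	639	wt	FALSE	TRUE	E640	.	480.000
R639I	639	mut	FALSE	FALSE	E640	.	476.500
Y78H	78	wt	FALSE	FALSE	L80	.	350.000
Y78H	78	mut	FALSE	FALSE	L80	.	352.200
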