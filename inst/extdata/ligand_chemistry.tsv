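# Ligand chemistry declarations, keyed by het code.
# categories: ring (ordered ring atom names), donor / acceptor
# (hydrogen-bond heavy atoms), cation / anion (charged-group atoms),
# named (reference atoms addressed by label, e.g. a hydroxyl or a
# bridging ether oxygen).
#
# SYNTHETIC NAMING: the UCN entry below describes the staurosporine-like
# ring systems and polar groups of 7-hydroxystaurosporine with generic
# atom names; deposited coordinate files may use different nomenclature,
# in which case supply an override table to read_ligand_chemistry().
het	category	label	atoms
UCN	ring	central_benzene	C1,C2,C3,C4,C5,C6
UCN	ring	indole_A	C7,C8,C9,C10,C11,C12
UCN	ring	indole_B	C13,C14,C15,C16,C17,C18
UCN	donor	lactam_NH	N1
UCN	donor	C7_hydroxyl	O7
UCN	donor	secondary_amine	N4
UCN	acceptor	lactam_carbonyl	O5
UCN	acceptor	C7_hydroxyl	O7
UCN	acceptor	bridging_oxygen	O6
UCN	acceptor	methoxy	O4
UCN	named	C7_OH	O7
UCN	named	bridging_O	O6
BNZ	ring	benzene	C1,C2,C3,C4,C5,C6
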