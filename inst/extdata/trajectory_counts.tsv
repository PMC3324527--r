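alloform	assembly	water	n_trajectories
Ab40	monomer	SPCE	44
Ab40	monomer	TIP3P	41
Ab40	dimer	SPCE	49
Ab40	dimer	TIP3P	42
Ab42	monomer	SPCE	45
Ab42	monomer	TIP3P	39
Ab42	dimer	SPCE	42
Ab42	dimer	TIP3P	41
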