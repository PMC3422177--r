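family	total	group	size	te_type
TF000572	610	a	11	tSINE
TF000572	610	b	18	tSINE
TF000572	610	c	11	tSINE
TF000573	507	a	13	tSINE
TF000574	279	a	100	tSINE
TF000574	279	b	39	tSINE
TF000574	279	c	64	tSINE
TF000574	279	d	10	tSINE
TF000580	289	a	25	mTA MITE
TF000580	289	b	22	mTA MITE
TF000672	112	a	11	m3bp MITE
TF000672	112	b	14	m3bp MITE
TF000708	270	a	25	m8bp MITE
TF000726	237	a	14	m9bp MITE
TF000728	257	a	116	mTA MITE
TF000730	258	a	10	mTA MITE
TF000738	318	a	18	mTA MITE
TF000738	318	b	14	mTA MITE
TF000742	294	a	146	ATon-I
TF000742	294	b	61	ATon-I
TF000742	294	c	17	ATon-I
TF000743	317	a	84	ATon-II
TF000743	317	b	15	ATon-II
TF000743	317	c	12	ATon-II
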