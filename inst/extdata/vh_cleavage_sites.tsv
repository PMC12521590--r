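accession	p1_position	protease	evidence
P10451	185	MMP3	literature
P10451	185	MMP7	literature
P98160	4195	BMP1	literature
P02768	174	MEP1B	literature
P02768	174	BACE2	literature
P02787	601	LGMN	literature
P02787	602	LGMN	literature
P10909	309	MMP3	literature
P10909	309	MMP12	literature
Q9BQT9	824	ADAMTS10	literature
Q9BQT9	824	ADAMTS17	literature
P02647	224	MMP7	literature
P02647	224	MMP12	literature
P02751	19	MMP2	literature
P02751	19	MMP8	literature
P02751	19	MMP13	literature
P02751	20	MMP2	literature
P02751	20	MMP8	literature
P02751	20	MMP13	literature
P0DJI8	22	CTSL1	literature
P0DJI8	22	MMP3	literature
P0DJI8	22	CTSB	literature
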