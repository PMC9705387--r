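family	s_spontaneum	kk3
INT	15	12
pGlcT	8	6
PLT	66	102
SFP	22	18
STP	83	78
SUT	19	8
SWEET	53	38
TST	13	32
VGT	7	0
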