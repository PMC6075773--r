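isoform	p91	p94	p95	p97	p98	p99	p102	p117	p118	p121	p122	p125	p126	p128	p178	p179	p181	p182	p185	p186	p189	p190	p193	p194	p197	p198	p200	p201	p204	p205	p208	p209	p212
TbAOX	S	T	C	W	L	F	F	S	R	F	L	V	A	V	P	L	V	S	I	T	I	M	F	L	A	Y	I	S	F	V	F	V	L
TaAOX1a-2AL.sv1	T	S	L	F	P	T	F	C	R	M	L	V	A	V	Y	E	A	L	A	V	V	F	A	Y	G	Y	I	S	F	A	V	V	L
TaAOX1a-2AL.sv2	T	S	L	F	P	T	F	C	R	M	L	V	A	V	Y	E	A	L	A	V	V	F	A	Y	G	Y	I	S	F	A	V	V	L
TaAOX1a-2BL	T	S	L	F	P	T	F	C	R	M	L	V	A	V	Y	E	A	L	A	V	V	F	A	Y	G	Y	I	S	F	A	V	V	L
TaAOX1a-2DL.sv1	T	S	L	F	P	T	F	C	R	M	L	V	A	V	Y	E	A	L	A	V	V	F	A	Y	G	Y	I	S	F	A	V	V	L
TaAOX1a-2DL.sv2	T	S	L	F	P	T	F	C	R	M	L	V	A	V	Y	E	A	L	A	V	V	F	A	Y	G	Y	I	S	F	A	V	V	L
TaAOX1a-like-2DL	-	-	-	-	-	-	-	-	-	-	-	-	-	-	Y	E	A	L	A	V	V	F	A	Y	G	Y	V	S	F	A	V	V	L
TaAOX1c-6AL	T	S	L	V	P	T	F	C	R	M	L	V	A	V	Y	E	A	L	A	V	V	F	A	Y	G	Y	I	S	F	A	V	V	L
TaAOX1c-6BL.sv1	T	S	L	V	P	T	F	C	R	M	L	V	A	V	Y	E	A	L	A	V	V	F	A	Y	G	Y	V	S	F	A	V	V	L
TaAOX1c-6BL.sv2	T	S	L	V	P	T	F	C	R	M	L	V	A	V	Y	E	A	L	A	V	V	F	A	Y	G	Y	V	S	F	A	V	V	L
TaAOX1c-6BL.sv3	T	S	L	V	P	T	F	C	R	M	L	V	A	V	Y	E	A	L	A	V	V	F	A	Y	G	Y	V	S	F	A	V	V	L
TaAOX1c-6DL	T	S	L	V	P	T	F	C	R	M	L	V	A	V	Y	E	A	L	A	V	V	F	A	Y	G	Y	V	S	F	A	V	V	L
put.TaAOX1e-3DS	T	A	I	W	P	T	F	C	R	M	L	V	A	V	Y	E	A	L	V	V	V	F	A	Y	T	Y	A	S	V	A	M	V	L
TaAOX1d-2AL.1	I	T	L	A	G	S	F	S	H	L	L	V	A	V	W	E	A	L	A	T	V	F	A	Y	G	Y	V	S	F	A	F	V	L
TaAOX1d-2AL.2.sv1	V	S	L	V	P	R	F	S	H	L	L	V	A	V	W	E	A	L	A	A	V	F	A	Y	G	Y	I	S	F	A	F	V	L
TaAOX1d-2AL.2.sv2	V	S	L	V	P	R	F	S	H	L	L	V	A	V	W	E	A	L	A	A	V	F	A	Y	G	Y	I	S	F	A	F	V	L
TaAOX1d-2DL	V	S	L	V	P	R	F	S	H	L	L	V	A	V	W	E	A	L	A	A	V	F	A	Y	G	Y	I	S	F	A	F	V	L
put.TaAOX1d-like-4AS	-	-	-	-	-	-	F	S	H	L	L	V	A	V	C	E	A	L	P	T	V	F	A	Y	G	Y	V	S	F	A	F	V	L
TuAOX1a	T	S	L	F	P	T	F	C	R	M	L	V	A	V	Y	E	A	L	A	V	V	F	A	Y	G	Y	I	S	F	A	V	V	L
TuAOX1c	T	S	L	V	P	T	F	C	R	M	L	V	A	V	Y	E	A	L	A	V	V	F	A	Y	G	Y	V	S	F	A	V	V	L
TuAOX1d.1	V	S	L	V	P	R	F	S	H	L	L	V	A	V	W	E	A	L	A	A	V	F	A	Y	G	Y	I	S	F	A	F	V	L
TuAOX1d.2	I	T	L	K	G	S	F	S	H	L	L	V	A	V	W	E	A	L	A	T	V	F	A	Y	G	Y	V	S	F	A	F	V	L
AetAOX1a	T	S	L	F	P	T	F	C	R	M	L	V	A	V	Y	E	A	L	A	V	V	F	A	Y	G	Y	I	S	F	A	V	V	L
AetAOX1e	T	A	M	W	P	T	F	C	R	M	L	V	A	V	Y	E	A	L	A	V	V	F	A	Y	T	Y	A	S	V	A	M	V	L
AetAOX1d	V	S	L	V	P	R	F	S	H	L	L	V	A	V	W	E	A	L	A	A	V	F	A	Y	G	Y	I	S	F	A	F	V	L
AetAOX1d-like	I	T	L	A	G	S	F	S	H	L	L	V	A	V	-	-	-	-	-	-	V	F	A	Y	G	Y	I	S	L	-	-	-	-
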