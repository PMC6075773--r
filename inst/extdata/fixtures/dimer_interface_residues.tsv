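isoform	p138	p142	p143	p163	p166	p187	p131	p135	p139	p141	p145	p147	p148	p156	p159	p167	p180	p183
TbAOX	H	L	R	R	L	Q	M	M	L	S	M	R	D	L	A	M	R	I
TaAOX1a-2AL.sv1	H	L	R	R	L	Q	M	M	L	S	F	Q	S	L	A	M	R	V
TaAOX1a-2AL.sv2	H	L	R	R	L	Q	M	M	L	S	F	Q	S	L	A	M	R	V
TaAOX1a-2BL	H	L	R	R	L	Q	M	M	L	S	F	Q	S	L	A	M	R	V
TaAOX1a-2DL.sv1	H	L	R	R	L	Q	M	M	L	S	F	Q	S	L	A	M	R	V
TaAOX1a-2DL.sv2	H	L	R	R	L	Q	M	M	L	S	F	Q	S	L	A	M	R	V
TaAOX1a-like-2DL	H	L	R	R	L	Q	M	V	L	S	F	H	S	M	A	M	R	V
TaAOX1c-6AL	H	L	R	R	L	Q	M	M	L	S	F	Q	S	L	A	M	R	V
TaAOX1c-6BL.sv1	H	L	R	R	L	Q	M	M	L	S	F	Q	S	L	A	M	R	V
TaAOX1c-6BL.sv2	H	L	R	R	L	Q	M	M	L	S	F	Q	S	L	A	M	R	V
TaAOX1c-6BL.sv3	H	L	R	R	L	Q	M	M	L	S	F	Q	S	L	A	M	R	V
TaAOX1c-6DL	H	L	R	R	L	Q	M	M	L	S	F	Q	S	L	A	M	R	V
put.TaAOX1e-3DS	H	L	R	R	L	Q	M	A	L	S	F	Q	S	L	A	M	R	V
TaAOX1d-2AL.1	H	L	R	R	L	Q	M	V	L	S	F	H	S	M	A	M	R	V
TaAOX1d-2AL.2.sv1	H	L	R	R	L	Q	M	V	L	S	F	H	S	M	A	M	R	V
TaAOX1d-2AL.2.sv2	H	L	R	R	L	Q	M	V	L	S	F	H	S	M	A	M	R	V
TaAOX1d-2DL	H	L	R	R	L	Q	M	V	L	S	F	H	S	M	A	M	R	V
put.TaAOX1d-like-4AS	H	L	R	R	L	Q	M	V	L	S	F	H	N	M	A	M	R	V
TuAOX1a	H	L	R	R	L	Q	M	M	L	S	F	Q	S	L	A	M	R	V
TuAOX1c	H	L	R	R	L	Q	M	M	L	S	F	Q	S	L	A	M	R	V
TuAOX1d.1	H	L	R	R	L	Q	M	V	L	S	F	H	S	M	A	M	R	V
TuAOX1d.2	H	L	R	R	L	Q	M	V	L	S	F	H	S	M	A	M	R	V
AetAOX1a	H	L	R	R	L	Q	M	M	L	S	F	Q	S	L	A	M	R	V
AetAOX1e	H	L	R	R	L	Q	M	A	L	S	F	Q	S	L	A	M	R	V
AetAOX1d	H	L	R	R	L	Q	M	V	L	S	F	H	S	M	A	M	R	V
AetAOX1d-like	H	L	R	R	L	-	M	V	L	S	F	H	S	M	A	M	-	-
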