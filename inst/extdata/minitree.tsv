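# synthetic phylotree-style mini-tree fixture;
# clade-defining variants follow published forms where available,
# backbone assignments are synthetic.
node	parent	variants
H2a2a1		
H	H2a2a1	A1438G
H3	H	A6776C
H3g	H3	C3915A
H3g1	H3g	A6253C
H7	H	C4793G
H7a	H7	A9150G
H7a1	H7a	C16261T
H7a1a	H7a1	A3396C @16261
H88	H	A10044G
H88a	H88	C5460A
H1	H	G3010A
H1j	H1	C13590A
H1j1	H1j	A6365C
R0a	H2a2a1	A2442C C13188T
JT	H2a2a1	T4216C A11251G
J	JT	C295T A12612G G13708A C16069T
J1	J	C462T G3010A
J1b	J1	C8557A
J1b3	J1b	A13934T
J1b3a	J1b3	A2158C
J1b3b	J1b3	C9932A
J1c	J1	G14798C
J1c1	J1c	G482C
J1c1b	J1c1	A5558T
J2	J	C7476T C15257A
J2b	J2	C5633T
J2b1	J2b	C12406A
J2b1c	J2b1	A16278T
T	JT	G1888A A4917G C8697A C13368A
T2	T	A11812G
U	H2a2a1	A11467G A12308G G12372A
U3	U	A13743C
U3b	U3	A4703C
U3b1	U3b	A15454C
U3b1c	U3b1	A2833G T7759C T8895C C11119T T12783C T15262C
U6	U	A3348G
U6a	U6	T7805A
K	U	T1189C A10550G T11299C C14167T
K1	K	C497T
K1a	K1	T10978G
K1a4	K1a	T6260A
N1	H2a2a1	G10238C
I	N1	A10034C
W	H2a2a1	A1243C
X	H2a2a1	A6221C A6371T
M	H2a2a1	C10400T T14783C G15043A
M5	M	T12477C
M5a	M5	C11884G
M5a1	M5a	A2772T
M5a1b	M5a1	A4454C
M5a1b1	M5a1b	C5319T
M5a1b1a	M5a1b1	T6680C
M5a1b1a1	M5a1b1a	C3921A
M18	M	C12498A
M35	M	C12561A
M1	M	C6446A A14110C
M1a	M1	A13780G
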