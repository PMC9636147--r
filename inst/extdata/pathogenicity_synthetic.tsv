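position	ref_aa	alt_aa	score
4252	I	L	0.293
4252	I	V	0.969
4252	I	F	0.591
5164	L	H	0.8
5164	L	P	0.892
5164	L	R	0.338
8622	I	M	0.086
13705	W	R	0.689
13705	W	G	0.116
10659	P	T	0.924
10659	P	A	0.785
10659	P	S	0.258
5935	Q	P	0.887
5935	Q	R	0.413
5935	Q	L	0.182
8463	P	H	0.672
8463	P	R	0.727
8463	P	L	0.84
8435	T	P	0.723
8435	T	A	0.061
8435	T	S	0.351
3449	K	T	0.344
3449	K	M	0.44
10765	K	N	0.188
3981	L	F	0.57
10562	M	I	0.149
11261	T	P	0.607
11261	T	A	0.307
11261	T	S	0.833
4639	L	H	0.627
4639	L	P	0.071
4639	L	R	0.871
10183	G	E	0.871
10183	G	A	0.194
10183	G	V	0.35
13831	N	H	0.32
13831	N	D	0.702
13831	N	Y	0.907
10110	V	I	0.89
10110	V	L	0.712
10110	V	F	0.56
6385	D	A	0.772
6385	D	G	0.359
6385	D	V	0.158
8372	E	K	0.071
8372	E	Q	0.374
10084	G	E	0.121
10084	G	A	0.84
10084	G	V	0.345
11456	L	I	0.08
11456	L	V	0.879
11456	L	F	0.494
4255	P	T	0.404
4255	P	A	0.389
4255	P	S	0.169
10235	L	F	0.769
10690	H	P	0.854
10690	H	R	0.376
10690	H	L	0.078
5914	P	Q	0.671
5914	P	R	0.905
5914	P	L	0.299
3971	*	K	0.049
3971	*	T	0.413
3971	*	M	0.412
5503	A	E	0.703
5503	A	G	0.175
5503	A	V	0.821
5304	A	T	0.164
5304	A	P	0.402
5304	A	S	0.933
7656	Y	S	0.41
7656	Y	C	0.316
7656	Y	F	0.981
8423	P	T	0.848
8423	P	A	0.691
8423	P	S	0.094
7064	Q	H	0.514
9405	T	P	0.138
9405	T	A	0.482
9405	T	S	0.906
11253	F	Y	0.169
11253	F	S	0.637
11253	F	C	0.217
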