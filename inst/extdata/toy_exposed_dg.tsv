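chain	position	aa	delta_g
H	1	S	0
H	2	N	0
H	3	S	0
H	4	T	0
H	5	Q	0
H	6	G	0
H	7	T	0
H	8	G	0
H	9	G	0
H	10	S	0
H	11	K	0
H	12	Q	0
H	13	T	0
H	14	T	0
H	15	S	0
H	16	Q	0
H	17	E	0
H	18	S	0
H	19	S	0
H	20	Q	0
H	21	Q	0
H	22	C	-0.000390076
H	23	T	0
H	24	T	0
H	25	S	0
H	26	N	0
H	27	S	0
H	28	N	0
H	29	G	0
H	30	T	0
H	31	T	0
H	32	N	0
H	33	N	0
H	34	N	0
H	35	T	0
H	36	N	0
H	37	S	0
H	38	S	0
H	39	N	0
H	40	S	0
H	41	T	0
H	42	G	0
H	43	T	0
H	44	T	0
H	45	Q	0
H	46	T	0
H	47	S	0
H	48	G	0
H	49	G	0
H	50	N	0
H	51	G	0
H	52	S	0
H	53	N	0
H	54	Q	0
H	55	S	0
H	56	E	0
H	57	N	0
H	58	Q	0
H	59	Q	0
H	60	N	0
H	61	Q	0
H	62	N	0
H	63	N	0
H	64	S	0
H	65	Q	0
H	66	Q	0
H	67	S	0
H	68	S	0
H	69	G	0
H	70	T	0
H	71	T	0
H	72	G	0
H	73	T	0
H	74	N	0
H	75	G	0
H	76	Q	0
H	77	T	0
H	78	T	0
H	79	S	0
H	80	G	0
H	81	G	0
H	82	T	0
H	83	T	0
H	84	E	0
H	85	T	0
H	86	Q	0
H	87	N	0
H	88	Q	0
H	89	N	0
H	90	S	0
H	91	G	0
H	92	C	-0.000390076
H	93	T	0
H	94	G	0
H	95	G	0
H	96	I	-0.122423
H	97	V	-0.0306673
H	98	I	-0.122423
H	99	V	-0.0306673
H	100	I	-0.122423
H	101	V	-0.0306673
H	102	S	0
H	103	W	0
H	104	G	0
H	105	Q	0
H	106	G	0
H	107	T	0
H	108	L	-0.114766
H	109	V	-0.0306673
H	110	T	0
H	111	V	-0.0306673
H	112	S	0
H	113	T	0
H	114	S	0
L	1	Q	0
L	2	N	0
L	3	N	0
L	4	S	0
L	5	Q	0
L	6	Q	0
L	7	S	0
L	8	G	0
L	9	G	0
L	10	G	0
L	11	G	0
L	12	N	0
L	13	S	0
L	14	S	0
L	15	N	0
L	16	T	0
L	17	S	0
L	18	T	0
L	19	G	0
L	20	N	0
L	21	S	0
L	22	G	0
L	23	C	-0.000390076
L	24	Q	0
L	25	G	0
L	26	N	0
L	27	T	0
L	28	S	0
L	29	N	0
L	30	S	0
L	31	N	0
L	32	T	0
L	33	Q	0
L	34	T	0
L	35	W	0
L	36	T	0
L	37	T	0
L	38	G	0
L	39	S	0
L	40	T	0
L	41	G	0
L	42	G	0
L	43	G	0
L	44	G	0
L	45	Q	0
L	46	G	0
L	47	S	0
L	48	T	0
L	49	N	0
L	50	T	0
L	51	T	0
L	52	N	0
L	53	Q	0
L	54	S	0
L	55	Q	0
L	56	Q	0
L	57	Q	0
L	58	N	0
L	59	N	0
L	60	N	0
L	61	T	0
L	62	S	0
L	63	G	0
L	64	S	0
L	65	S	0
L	66	N	0
L	67	Q	0
L	68	S	0
L	69	G	0
L	70	N	0
L	71	Q	0
L	72	N	0
L	73	S	0
L	74	S	0
L	75	Q	0
L	76	Q	0
L	77	S	0
L	78	Q	0
L	79	N	0
L	80	T	0
L	81	T	0
L	82	S	0
L	83	Q	0
L	84	Q	0
L	85	T	0
L	86	Q	0
L	87	T	0
L	88	C	-0.000390076
L	89	N	0
L	90	T	0
L	91	Q	0
L	92	Q	0
L	93	N	0
L	94	N	0
L	95	S	0
L	96	T	0
L	97	F	-0.151711
L	98	G	0
L	99	G	0
L	100	G	0
L	101	T	0
L	102	K	0
L	103	L	-0.114766
L	104	E	0
L	105	I	-0.122423
L	106	K	0
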