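sample_id	field_type	plant	injury
C01	CHY	1	8
C01	CHY	2	11
C01	CHY	3	23
C02	CHY	1	22
C02	CHY	2	22
C02	CHY	3	23
C03	CHY	1	5
C03	CHY	2	11
C03	CHY	3	19
C04	CHY	1	7
C04	CHY	2	8
C04	CHY	3	23
C05	CHY	1	14
C05	CHY	2	16
C05	CHY	3	18
C06	CHY	1	9
C06	CHY	2	10
C06	CHY	3	22
C07	CHY	1	1
C07	CHY	2	2
C07	CHY	3	18
C08	CHY	1	4
C08	CHY	2	23
C08	CHY	3	24
C09	CHY	1	21
C09	CHY	2	24
C09	CHY	3	24
C10	CHY	1	7
C10	CHY	2	13
C10	CHY	3	14
C11	CHY	1	1
C11	CHY	2	4
C11	CHY	3	18
C12	CHY	1	4
C12	CHY	2	5
C12	CHY	3	19
C13	CHY	1	2
C13	CHY	2	20
C13	CHY	3	22
C14	CHY	1	5
C14	CHY	2	6
C14	CHY	3	17
C15	CHY	1	2
C15	CHY	2	8
C15	CHY	3	100
H16	HYB	1	3
H16	HYB	2	16
H16	HYB	3	17
H17	HYB	1	7
H17	HYB	2	13
H17	HYB	3	18
H18	HYB	1	15
H18	HYB	2	17
H18	HYB	3	18
H19	HYB	1	4
H19	HYB	2	10
H19	HYB	3	19
H20	HYB	1	2
H20	HYB	2	3
H20	HYB	3	14
H21	HYB	1	5
H21	HYB	2	8
H21	HYB	3	19
H22	HYB	1	0
H22	HYB	2	10
H22	HYB	3	13
H23	HYB	1	3
H23	HYB	2	8
H23	HYB	3	17
H24	HYB	1	2
H24	HYB	2	10
H24	HYB	3	24
H25	HYB	1	16
H25	HYB	2	19
H25	HYB	3	21
H26	HYB	1	13
H26	HYB	2	19
H26	HYB	3	20
H27	HYB	1	4
H27	HYB	2	8
H27	HYB	3	22
H28	HYB	1	45
H28	HYB	2	54
H28	HYB	3	60
H29	HYB	1	44
H29	HYB	2	57
H29	HYB	3	60
H30	HYB	1	82
H30	HYB	2	83
H30	HYB	3	98
H31	HYB	1	87
H31	HYB	2	91
H31	HYB	3	92
H32	HYB	1	11
H32	HYB	2	11
H32	HYB	3	91
H33	HYB	1	9
H33	HYB	2	14
H33	HYB	3	92
H34	HYB	1	15
H34	HYB	2	17
H34	HYB	3	93
C35	CLF	1	1
C35	CLF	2	19
C35	CLF	3	22
C36	CLF	1	17
C36	CLF	2	18
C36	CLF	3	24
C37	CLF	1	0
C37	CLF	2	7
C37	CLF	3	9
C38	CLF	1	18
C38	CLF	2	20
C38	CLF	3	25
C39	CLF	1	7
C39	CLF	2	17
C39	CLF	3	19
C40	CLF	1	5
C40	CLF	2	6
C40	CLF	3	16
C41	CLF	1	10
C41	CLF	2	14
C41	CLF	3	24
C42	CLF	1	9
C42	CLF	2	13
C42	CLF	3	19
C43	CLF	1	45
C43	CLF	2	52
C43	CLF	3	59
C44	CLF	1	41
C44	CLF	2	45
C44	CLF	3	48
C45	CLF	1	3
C45	CLF	2	6
C45	CLF	3	95
C46	CLF	1	11
C46	CLF	2	15
C46	CLF	3	95
C47	CLF	1	2
C47	CLF	2	15
C47	CLF	3	99
C48	CLF	1	7
C48	CLF	2	9
C48	CLF	3	94
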