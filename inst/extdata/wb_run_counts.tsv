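condition	n_animals	region	pieces	GluN1	GluN2A	GluN2B	GABAAa1	GABAAa3	GluA2	Synapsin
5wk_normal	1	C	2	4	4	4	4	4	4	4
5wk_normal	1	P	8	16	16	16	15	16	16	16
5wk_normal	1	M	2	4	4	4	4	4	4	4
MD	2	C	3	6	6	6	6	6	6	4
MD	2	P	9	18	18	18	18	18	18	12
MD	2	M	3	5	5	5	5	5	5	4
RO	1	C	2	4	4	4	4	4	4	4
RO	1	P	8	19	19	19	19	19	14	14
RO	1	M	2	3	3	3	3	3	2	2
BD	1	C	3	6	6	5	6	5	6	5
BD	1	P	9	18	18	17	16	18	18	17
BD	1	M	2	4	4	3	4	4	4	3
ST-BV	2	C	4	8	8	8	8	8	8	8
ST-BV	2	P	16	32	32	32	32	32	32	32
ST-BV	2	M	4	8	8	8	8	8	8	7
LT-BV	3	C	6	12	10	12	11	12	12	10
LT-BV	3	P	24	43	40	43	43	42	43	40
LT-BV	3	M	6	12	12	12	12	12	12	12
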