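species	total_hs	pseudo_hs	total_hgt	pseudo_hgt	total_all	pseudo_all
Gorilla	86	27	20	5	106	32
Pongo	104	25	19	5	123	30
Gibbon	88	12	14	3	102	15
Callitrix	83	13	24	8	107	21
Tarsius	63	15	27	3	90	18
MouseLemur	78	16	18	5	96	21
Otolemur	50	16	20	2	70	18
Treeshrew	73	14	28	7	101	21
Cavia	115	13	39	4	154	17
Rabbit	99	14	25	3	124	17
Dolphin	18	13	17	13	35	26
Cow	113	21	32	1	145	22
Pig	76	16	26	3	102	19
Alpaca	46	14	25	3	71	17
Horse	91	8	34	4	125	12
Panda	72	15	29	6	101	21
Bat	71	17	29	7	100	24
Hedgehog	70	10	17	4	87	14
Elephant	88	18	24	4	112	22
Armadillo	58	21	27	0	85	21
Sloth	114	27	61	7	175	34
Wallaby	63	10	40	0	103	10
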