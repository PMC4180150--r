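subfamily	class	Gorilla	Pongo	Gibbon	Callitrix	Tarsius	MouseLemur	Otolemur	Treeshrew	Cavia	Rabbit	Dolphin	Cow	Pig	Alpaca	Horse	Panda	Bat	Hedgehog	Elephant	Armadillo	Sloth	Wallaby
KRTAP1	HS	4(2)	4(0)	3(0)	4(1)	4(0)	4(0)	4(0)	2(1)	4(0)	4(0)	0(0)	4(0)	4(1)	5(1)	4(0)	3(0)	4(1)	4(1)	4(0)	2(0)	4(1)	4(1)
KRTAP2	HS	4(0)	3(0)	4(0)	4(0)	3(0)	4(0)	2(0)	5(1)	4(0)	4(0)	0(0)	4(0)	4(0)	3(0)	4(0)	5(1)	3(0)	4(1)	4(0)	4(0)	3(0)	5(0)
KRTAP3	HS	3(0)	6(0)	4(1)	4(0)	3(0)	2(0)	4(1)	2(1)	4(0)	4(0)	2(2)	4(0)	4(0)	5(2)	4(0)	4(1)	4(0)	4(0)	4(1)	3(1)	4(0)	4(0)
KRTAP4	HS	15(6)	15(4)	10(2)	8(1)	8(1)	9(2)	14(3)	12(1)	16(1)	14(1)	0(0)	16(5)	7(0)	7(3)	12(0)	4(1)	6(0)	8(1)	13(4)	9(3)	8(0)	17(4)
KRTAP5	HS	13(8)	14(6)	15(3)	19(5)	16(8)	8(4)	13(2)	11(4)	18(5)	18(1)	1(1)	18(5)	0(0)	2(2)	11(2)	13(3)	6(4)	5(0)	12(4)	8(7)	8(1)	7(1)
KRTAP9	HS	9(2)	12(2)	9(1)	5(0)	6(1)	4(1)	8(0)	5(0)	12(2)	6(1)	0(0)	19(3)	5(0)	4(1)	8(2)	2(0)	9(3)	9(1)	4(0)	7(2)	50(5)	0(0)
KRTAP10	HS	13(5)	17(2)	13(0)	13(2)	8(2)	5(1)	7(1)	10(2)	12(1)	10(2)	2(2)	15(3)	14(1)	1(1)	11(0)	8(1)	14(5)	1(1)	8(1)	3(1)	1(0)	5(3)
KRTAP11	HS	1(0)	1(0)	1(0)	1(0)	1(0)	1(0)	1(0)	1(0)	1(0)	1(0)	1(1)	1(0)	1(0)	1(0)	1(0)	1(0)	1(0)	1(1)	1(0)	0(0)	1(0)	1(0)
KRTAP12	HS	3(0)	4(2)	2(0)	3(2)	0(0)	0(0)	3(1)	1(0)	12(1)	0(0)	1(0)	6(0)	4(0)	1(0)	10(1)	5(1)	1(0)	10(1)	11(2)	1(0)	5(2)	7(0)
KRTAP13	HS	4(2)	8(4)	7(3)	6(1)	4(2)	4(2)	8(0)	6(1)	8(2)	8(3)	10(6)	8(3)	14(10)	8(0)	10(2)	8(1)	12(3)	7(1)	11(5)	9(5)	16(13)	0(0)
KRTAP16	HS	1(0)	2(1)	1(0)	1(0)	0(0)	0(0)	1(0)	1(0)	1(0)	1(0)	0(0)	1(0)	0(0)	1(0)	1(0)	1(0)	1(0)	2(1)	1(0)	1(0)	2(1)	1(0)
KRTAP17	HS	1(0)	1(0)	1(0)	1(0)	0(0)	1(0)	1(1)	1(0)	1(0)	1(0)	0(0)	1(0)	1(0)	0(0)	1(0)	1(0)	1(0)	0(0)	1(0)	0(0)	1(0)	1(0)
KRTAP24	HS	1(0)	2(0)	1(0)	1(0)	1(0)	1(0)	1(1)	1(0)	1(0)	1(0)	0(0)	1(0)	1(1)	1(0)	1(0)	1(0)	1(0)	1(0)	1(0)	1(0)	1(0)	0(0)
KRTAP25	HS	1(1)	1(1)	1(0)	0(0)	0(0)	1(1)	0(0)	1(1)	0(0)	1(1)	0(0)	0(0)	1(1)	1(1)	1(0)	1(0)	1(1)	0(0)	0(0)	0(0)	0(0)	0(0)
KRTAP26	HS	2(1)	1(0)	2(0)	1(0)	1(0)	1(1)	1(1)	1(0)	1(0)	1(0)	1(1)	2(0)	1(0)	1(0)	1(0)	1(0)	1(0)	1(0)	3(0)	1(0)	4(1)	0(0)
KRTAP27	HS	1(0)	1(0)	1(0)	1(0)	1(0)	1(1)	0(0)	1(0)	1(0)	1(0)	0(0)	1(0)	1(0)	1(0)	1(0)	1(0)	1(0)	1(1)	1(0)	1(0)	0(0)	0(0)
KRTAP28	HS	9(0)	11(1)	12(2)	10(1)	7(1)	4(3)	9(4)	11(3)	19(1)	23(5)	0(0)	10(2)	14(2)	2(2)	9(1)	12(6)	4(0)	11(0)	8(1)	7(2)	5(2)	10(1)
KRTAP29	HS	1(0)	1(1)	1(0)	1(0)	0(0)	0(0)	1(1)	1(0)	0(0)	1(0)	0(0)	2(0)	0(0)	2(2)	1(0)	1(0)	1(0)	1(0)	1(0)	1(0)	1(1)	1(0)
KRTAP30	HS	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)
KRTAP31	HS	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)
KRTAP32	HS	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)
KRTAP33	HS	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)
KRTAP34	HS	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)
KRTAP35	HS	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)	0(0)
KRTAP6	HGT	4(1)	3(1)	3(0)	3(0)	8(0)	4(0)	4(1)	5(0)	7(1)	9(1)	1(1)	5(0)	4(0)	9(0)	4(0)	7(2)	6(0)	4(1)	5(1)	0(0)	0(0)	0(0)
KRTAP7	HGT	1(0)	1(0)	1(0)	1(0)	1(0)	2(0)	2(0)	1(0)	1(0)	1(0)	1(1)	1(0)	1(0)	1(0)	1(0)	1(0)	1(0)	1(0)	1(1)	1(0)	1(0)	1(0)
KRTAP8	HGT	1(0)	1(0)	1(0)	1(0)	2(0)	0(0)	0(0)	1(1)	1(0)	1(0)	3(0)	2(0)	4(1)	0(0)	3(1)	1(0)	1(0)	1(0)	1(0)	1(0)	4(2)	1(0)
KRTAP19	HGT	8(3)	9(4)	5(3)	9(5)	10(3)	5(0)	6(0)	9(2)	0(0)	2(0)	6(5)	8(1)	3(2)	0(0)	8(2)	8(3)	7(2)	4(0)	6(1)	0(0)	7(1)	0(0)
KRTAP20	HGT	2(0)	2(0)	1(0)	2(1)	4(0)	6(1)	5(1)	10(3)	27(3)	8(1)	6(6)	5(0)	5(0)	12(2)	12(0)	4(0)	6(3)	2(2)	6(1)	12(0)	37(3)	38(0)
KRTAP21	HGT	4(1)	3(0)	3(0)	8(2)	2(0)	3(1)	3(1)	2(1)	3(0)	4(1)	0(0)	11(0)	9(0)	3(1)	6(1)	8(1)	8(2)	5(1)	5(0)	13(0)	12(1)	0(0)
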