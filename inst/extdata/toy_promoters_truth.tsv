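seq_id	start_1based	end_1based	strand	text
promoter01	1	8	+	TGAATCAT
promoter02	387	394	+	TTACTCAT
promoter04	109	116	+	TGACTCAT
promoter04	122	129	+	TGACTCAT
promoter06	193	200	+	TGACCCAT
promoter06	208	215	+	TGACTCTT
promoter08	33	40	+	TGACTCCT
promoter08	72	79	+	TGACTCAT
promoter08	208	215	+	TGGCTCAT
promoter08	342	349	+	TGATTCAT
promoter09	153	160	+	TGTCTCAT
promoter10	315	322	+	TGACTCAT
promoter11	48	55	+	TGCCTCAT
promoter11	280	287	+	TGACTCCT
promoter11	373	380	+	TGACTCAT
promoter12	104	111	+	TGACTCAT
promoter16	110	117	+	TGACTCAT
promoter16	167	174	+	TGACTCAT
promoter19	28	35	+	TGACTCAT
promoter19	130	137	+	TGACTCAC
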