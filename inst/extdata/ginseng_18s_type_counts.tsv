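# Directed substitution-type counts tallied over cloned 18S rDNA copies
# of three cultivated Panax ginseng cell lines (9s: young stem line;
# 1s/1o: long-term stem and ovary lines) and a plant control.
# n_clones: number of sequenced clones per line.
line	n_clones	A>G	T>C	G>A	C>T	A>T	A>C	T>A	T>G	G>T	C>G	G>C	C>A
9s	20	10	19	7	2	0	0	1	1	1	0	0	0
1s	46	49	39	23	55	43	7	6	1	5	1	4	7
1o	46	38	34	28	24	10	4	4	2	3	1	1	1
plant	30	10	12	11	4	0	0	0	1	2	1	0	1
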