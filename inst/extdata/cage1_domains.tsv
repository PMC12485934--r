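# cagekit reference fixture: domain parsing of the Tetrahymena CAGE1 protein (UniProt I7MLD7)
# residues 2216
domain	start	end
1	1	105
2	142	443
3	444	555
3	1036	1041
4	556	635
5	636	748
6	758	843
7	851	951
8	963	1021
8	1151	1195
9	1073	1080
9	1496	1500
9	1852	1857
10	1215	1244
10	1565	1598
11	1244	1414
11	1519	1559
12	1606	1738
13	1751	1833
14	1879	2011
15	2014	2215
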