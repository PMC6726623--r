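legacy_name	cdna_name	protein_name	classification	asserted_date	tract_modifier	chrom	pos	ref	alt
Q39X	c.115C>T	p.Gln39Ter	CF causing			7	117100115	C	T
L88X	c.263T>G	p.Leu88Ter	CF causing			7	117100263	T	G
R117H	c.350G>A	p.Arg117His	Varying clinical consequence		T5/TG11	7	117100350	G	A
c.489+1G>T	c.489+1G>T		CF causing			7	117100490	G	T
L206W	c.617T>G	p.Leu206Trp	CF causing			7	117100617	T	G
R334W	c.1000C>T	p.Arg334Trp	CF causing			7	117101000	C	T
F508del	c.1521_1523delCTT	p.Phe508del	CF causing			7	117101520	ACTT	A
G542X	c.1624G>T	p.Gly542Ter	CF causing			7	117101624	G	T
G551D	c.1652G>A	p.Gly551Asp	CF causing			7	117101652	G	A
K710X	c.2128A>T	p.Lys710Ter	CF causing			7	117102128	A	T
S1235R	c.3705T>G	p.Ser1235Arg	Non CF-causing			7	117103705	T	G
c.3718-2477C>T	c.3718-2477C>T		CF causing			7	117103800	C	T
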