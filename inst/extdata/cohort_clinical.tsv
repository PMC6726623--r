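sample_id	legacy_name	zygosity	call_date	comparable
CASE01	F508del	HOM_ALT	2015-06-01	yes
CASE02	F508del	HOM_ALT	2015-06-01	yes
CASE03	F508del	HOM_ALT	2015-06-01	yes
CASE04	F508del	HOM_ALT	2015-06-01	yes
CASE05	F508del	HOM_ALT	2015-06-01	yes
CASE06	F508del	HOM_ALT	2015-06-01	yes
CASE07	F508del	HOM_ALT	2015-06-01	yes
CASE08	F508del	HOM_ALT	2015-06-01	yes
CASE09	F508del	HOM_ALT	2015-06-01	yes
CASE10	F508del	HOM_ALT	2015-06-01	yes
CASE11	F508del	HOM_ALT	2015-06-01	yes
CASE12	F508del	HOM_ALT	2015-06-01	yes
CASE13	F508del	HOM_ALT	2015-06-01	yes
CASE16	F508del	HET	2015-06-01	yes
CASE16	L88X	HET	2015-06-01	yes
CASE17	F508del	HET	2015-06-01	yes
CASE17	R117H	HET	2015-06-01	yes
CASE18	c.489+1G>T	HET	2015-06-01	yes
CASE18	c.3718-2477C>T	HET	2015-06-01	yes
CASE19	R334W	HET	2015-06-01	yes
CASE19	G542X	HET	2015-06-01	yes
CASE20	F508del	HET	2015-06-01	yes
CASE20	G551D	HET	2015-06-01	yes
CASE21	F508del	HET	2015-06-01	yes
CASE21	K710X	HET	2015-06-01	yes
CASE22	F508del	HET	2015-06-01	yes
CASE22	R1239S	HET	2015-06-01	yes
CASE26	F508del	HET	2009-06-01	no
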