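sample_id	age_years	sex
CASE01	6	M
CASE02	19	F
CASE03	20	F
CASE04	21	F
CASE05	27	M
CASE06	29	M
CASE07	30	F
CASE08	34	M
CASE09	37	F
CASE10	38	F
CASE11	41	F
CASE12	45	M
CASE13	54	M
CASE14	55	F
CASE15	37	M
CASE16	6	M
CASE17	23	F
CASE18	37	F
CASE19	22	F
CASE20	29	F
CASE21	45	M
CASE22	5	M
CASE23	7	F
CASE24	62	M
CASE25	74	M
CASE26	68	F
EHR01	33	F
EHR02	47	M
EHR03	52	F
EHR04	28	M
EHR05	61	F
EHR06	39	M
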