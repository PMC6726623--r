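sample_id	sweat_values	clinical_variants	bronchiectasis	pancreatic_supplement	respiratory_pseudomonas	cf_clinic_care	cf_dx_in_ehr
CASE01	93	F508del;F508del	unknown	yes	unknown	yes	yes
CASE02	92	F508del;F508del	unknown	yes	unknown	yes	yes
CASE03	91	F508del;F508del	yes	yes	yes	yes	yes
CASE04	QNS	F508del;F508del	unknown	yes	yes	yes	yes
CASE05	112	F508del;F508del	yes	yes	yes	yes	yes
CASE06	90	F508del;F508del	unknown	yes	yes	yes	yes
CASE07	82	F508del;F508del	yes	yes	yes	yes	yes
CASE08	91	F508del;F508del	unknown	yes	unknown	yes	yes
CASE09	69	F508del;F508del	yes	yes	yes	yes	yes
CASE10	-	F508del;F508del	yes	yes	yes	yes	yes
CASE11	97	F508del;F508del	yes	yes	yes	yes	yes
CASE12	-	F508del;F508del	unknown	yes	unknown	yes	yes
CASE13	108	F508del;F508del	yes	yes	yes	yes	yes
CASE14	-	-	unknown	yes	yes	yes	yes
CASE15	-	-	unknown	unknown	unknown	yes	yes
CASE16	73	F508del;L88X	unknown	yes	yes	yes	yes
CASE17	-	F508del;R117H	unknown	yes	unknown	yes	yes
CASE18	50	c.489+1G>T;c.3718-2477C>T	unknown	yes	yes	yes	yes
CASE19	103	R334W;G542X	unknown	yes	unknown	yes	yes
CASE20	90	F508del;G551D	unknown	yes	yes	yes	yes
CASE21	91	F508del;K710X	unknown	yes	unknown	yes	yes
CASE22	66	F508del;R1239S	unknown	yes	unknown	yes	yes
CASE23	<10;14	F508del;S1235R	unknown	unknown	yes	yes	yes
CASE24	-	-	unknown	unknown	unknown	no	no
CASE25	-	-	unknown	unknown	unknown	no	no
CASE26	-	F508del	yes	unknown	yes	no	no
EHR01	-	-	unknown	unknown	unknown	no	yes
EHR02	-	-	unknown	unknown	unknown	no	yes
EHR03	-	-	unknown	unknown	unknown	no	yes
EHR04	-	-	unknown	unknown	unknown	no	yes
EHR05	-	-	unknown	unknown	unknown	no	yes
EHR06	-	-	unknown	unknown	unknown	no	yes
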