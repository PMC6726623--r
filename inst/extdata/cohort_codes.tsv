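sample_id	icd10_code
CASE01	E84.0
CASE02	E84.0
CASE03	E84.0
CASE04	E84.0
CASE05	E84.0
CASE05	E84.19
CASE06	E84.0
CASE07	E84.0
CASE08	E84.0
CASE09	E84.0
CASE10	E84.0
CASE11	E84.0
CASE12	E84.0
CASE13	E84.0
CASE14	E84.0
CASE15	E84.0
CASE16	E84.0
CASE17	E84.0
CASE18	E84.0
CASE19	E84.0
CASE20	E84.0
CASE21	E84.0
CASE22	E84.9
CASE23	E84.9
EHR01	E84.9
EHR02	E84.9
EHR03	E84.9
EHR04	E84.9
EHR05	E84.9
EHR06	E84.9
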