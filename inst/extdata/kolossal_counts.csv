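strategy,stratum,n,prox_an_total,colonoscopies,prox_an_detected,crc_detected,crc_total,aa_detected,aa_total,an_detected,an_total
no_referral,men,7323,359,0,0,118,140,646,971,752,1111
uk,men,7323,359,965,114,126,140,740,971,866,1111
score,men,7323,359,1146,125,126,140,751,971,877,1111
norccap,men,7323,359,2004,162,127,140,787,971,914,1111
plco,men,7323,359,4167,270,135,140,887,971,1022,1111
ge2_neoplasms_ge1_an,men,7323,359,395,56,122,140,686,971,808,1111
ge2_neoplasms,men,7323,359,630,74,123,140,703,971,826,1111
histology_an,men,7323,359,617,75,124,140,703,971,827,1111
an_ge_10mm,men,7323,359,639,76,122,140,706,971,828,1111
any_an,men,7323,359,854,102,125,140,729,971,854,1111
any_neoplasm,men,7323,359,1941,156,127,140,781,971,908,1111
any_neoplasm_or_hpp,men,7323,359,2737,191,127,140,816,971,943,1111
no_referral,women,7624,222,0,0,51,73,345,544,395,617
uk,women,7624,222,456,29,52,73,372,544,424,617
score,women,7624,222,586,34,52,73,377,544,429,617
norccap,women,7624,222,1216,58,57,73,396,544,453,617
plco,women,7624,222,1062,50,57,73,388,544,445,617
ge2_neoplasms_ge1_an,women,7624,222,152,11,52,73,354,544,406,617
ge2_neoplasms,women,7624,222,263,16,53,73,358,544,411,617
histology_an,women,7624,222,307,20,52,73,363,544,415,617
an_ge_10mm,women,7624,222,314,16,52,73,359,544,411,617
any_an,women,7624,222,422,27,52,73,370,544,422,617
any_neoplasm,women,7624,222,1186,56,57,73,394,544,451,617
any_neoplasm_or_hpp,women,7624,222,1874,74,57,73,412,544,469,617
no_referral,both,14947,581,0,0,169,213,991,1515,1147,1728
uk,both,14947,581,1421,143,178,213,1112,1515,1290,1728
score,both,14947,581,1732,159,178,213,1128,1515,1306,1728
norccap,both,14947,581,3220,220,184,213,1183,1515,1367,1728
plco,both,14947,581,5229,320,192,213,1275,1515,1467,1728
ge2_neoplasms_ge1_an,both,14947,581,547,67,174,213,1040,1515,1214,1728
ge2_neoplasms,both,14947,581,893,90,176,213,1061,1515,1237,1728
histology_an,both,14947,581,924,95,176,213,1066,1515,1242,1728
an_ge_10mm,both,14947,581,953,92,174,213,1065,1515,1239,1728
any_an,both,14947,581,1276,129,177,213,1099,1515,1276,1728
any_neoplasm,both,14947,581,3127,212,184,213,1175,1515,1359,1728
any_neoplasm_or_hpp,both,14947,581,4611,265,184,213,1228,1515,1412,1728
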