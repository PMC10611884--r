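"name","pesticide_class","chemical_class","molar_mass_g_mol","koc_exp_L_kg","koc_model_L_kg","log_kow","pka","dt50_soil_days","dt50_water_days"
"2,4-D","herbicide","phenoxy acid (synthetic auxin)",221.04,39.3,53.06,-0.82,2.87,10,7.80643
"ametryn","herbicide","triazine (PSII inhibitor)",227.33,316,426.6,2.63,4.1,37,30.0599
"amicarbazone","herbicide","triazolinone (PSII inhibitor)",241.29,,32,1.18,,50,25.4622
"asulam","herbicide","carbamate",230.24,40,54,-0.22,4.82,7,29.8388
"atrazine","herbicide","triazine (PSII inhibitor)",215.68,100,135,2.7,1.7,75,79.9817
"bifenthrin","insecticide","pyrethroid",422.87,236610,319400,6.6,,86,89
"cadusafos","insecticide","organophosphate",270.39,227,306.5,3.9,,39,30.3352
"carbofuran","insecticide","carbamate",221.26,22,29.7,1.8,,14,9.76687
"chlorothalonil","fungicide","chloronitrile",265.91,850,1148,2.94,,2.5,0.541318
"chlorpyrifos","insecticide","organophosphate",350.59,5509,7437,4.7,,27.6,10.1493
"clothianidin","insecticide","neonicotinoid",249.68,123,166,0.905,11.1,545,39.998
"dicamba","herbicide","benzoic acid (synthetic auxin)",221.04,,12,-1.88,1.87,14,21.9981
"diquat dibromide","herbicide","bipyridylium",344.05,2184000,1139.3,-4.6,,5500,30
"diuron","herbicide","phenylurea (PSII inhibitor)",233.09,813,1098,2.87,,146,9.50427
"fipronil","insecticide","phenylpyrazole",437.15,,727,4,,142,53.1753
"fluazifop-P-butyl","herbicide","aryloxyphenoxypropionate",383.36,3394,4582,4.5,,8.2,137.505
"fluensulfone","nematicide","fluoroalkenyl sulfone",291.71,,130,1.92,,12,12.1566
"flumioxazin","herbicide","N-phenylphthalimide",354.34,889,1200,2.55,,17.7,2.40161
"fluroxypyr","herbicide","pyridine carboxylic acid (synthetic auxin)",255.03,,80,0.04,2.94,13.5,10.0263
"flutriafol","fungicide","triazole",301.29,205,276.8,2.3,,1358,46.4115
"glufosinate ammonium","herbicide","phosphinic acid",198.16,600,810,-3.96,2,7.4,7.28469
"glyphosate","herbicide","phosphonoglycine",169.07,1424,1922,-3.2,2.34,23.8,6.86154
"halosulfuron-methyl","herbicide","sulfonylurea",434.81,,75,-0.02,3.44,14,14.1234
"haloxyfop","herbicide","aryloxyphenoxypropionate",361.7,,58,1.34,2.9,9,11.4469
"hexazinone","herbicide","triazinone (PSII inhibitor)",252.31,54,72.9,1.17,,105,55.9981
"imazapic","herbicide","imidazolinone",275.3,,137,0.393,3.9,31,1.10012
"imidacloprid","insecticide","neonicotinoid",255.66,225,303.8,0.57,,191,35.5096
"isoxaflutole","herbicide","isoxazole",359.32,145,195.8,2.34,,1.3,0.266092
"MCPA","herbicide","phenoxy acid (synthetic auxin)",200.62,74,99.9,-0.71,3.73,24,14.5812
"metolachlor","herbicide","chloroacetamide",283.79,120,162,3.4,,90,71.534
"metribuzin","herbicide","triazinone (PSII inhibitor)",214.29,38,51.3,1.65,0.99,19,38.1041
"metsulfuron-methyl","herbicide","sulfonylurea",381.36,,39.5,-1.87,3.75,52,22.3733
"MSMA","herbicide","organoarsenic",161.95,,100,-3.1,4.1,1000,7.13721
"paraquat dichloride","herbicide","bipyridylium",257.16,1e+06,1067.2,-4.5,,3000,7
"pendimethalin","herbicide","dinitroaniline",281.31,17491,23610,5.4,,100,21
"permethrin","insecticide","pyrethroid",391.29,1e+05,135000,6.1,,13,19
"picloram","herbicide","pyridine carboxylic acid (synthetic auxin)",241.46,13,17.55,-1.92,2.3,82.8,80.9946
"propiconazole","fungicide","triazole",342.22,1086,1466,3.72,1.09,71.8,6.03845
"S-metolachlor","herbicide","chloroacetamide",283.79,,226,3.05,,15,29.8643
"tebuconazole","fungicide","triazole",307.82,769,1038,3.7,,63,38.2429
"terbuthylazine","herbicide","triazine (PSII inhibitor)",229.71,231,311.8,3.4,1.9,72,8.61974
"terbutryn","herbicide","triazine (PSII inhibitor)",241.36,2432,3283,3.66,4.3,74,26.9945
"triadimenol","fungicide","triazole",295.76,,273,3.18,,250,36.9094
"trichlorfon","insecticide","organophosphate",257.44,,10,0.43,,4.5,4.59026
"trifloxysulfuron sodium","herbicide","sulfonylurea",459.33,,35,-0.43,4.76,24,31.2965
"trifluralin","herbicide","dinitroaniline",335.28,15800,21330,5.34,,181,1.1
"trinexapac-ethyl","herbicide","cyclohexanedione",252.31,,245,-0.29,4.57,1.2,0.775206
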