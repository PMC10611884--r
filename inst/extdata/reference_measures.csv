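"label","name","product_name","pesticide_class","mobility_persistence","effect_max","aquatic_risk","aquatic_risk_reported","risk_reported_printed"
"2,4-D","2,4-D","standard","herbicide",18,52,936,9.36,"9"
"ametryn","ametryn","standard","herbicide",155,20000,3100000,31000,"31000"
"amicarbazone","amicarbazone","standard","herbicide",305,350,106750,1067.5,"1100"
"asulam","asulam","standard","herbicide",48,16,768,7.68,"8"
"atrazine","atrazine","standard","herbicide",1138,782,889916,8899.16,"8900"
"bifenthrin","bifenthrin","standard","insecticide",0.01,208333,2083.33,20.8333,"21"
"cadusafos","cadusafos","standard","insecticide",182,2197802,399999964,3999999.64,"4000000"
"carbofuran","carbofuran","standard","insecticide",35,1500,52500,525,"520"
"chlorothalonil","chlorothalonil","standard","fungicide",0.13,3450,448.5,4.485,"5"
"chlorpyrifos","chlorpyrifos","standard","insecticide",4,21276596,85106384,851063.84,"850000"
"clothianidin","clothianidin","standard","insecticide",3938,1724,6789112,67891.12,"68000"
"dicamba","dicamba","standard","herbicide",87,5,435,4.35,"4"
"diquat dibromide","diquat dibromide","standard","herbicide",0.01,335,3.35,0.0335,"<1"
"diuron","diuron","standard","herbicide",136,2478,337008,3370.08,"3400"
"fipronil","fipronil","standard","insecticide",777,5618,4365186,43651.86,"43600"
"fluazifop-P-butyl","fluazifop-P-butyl","standard","herbicide",40,48,1920,19.2,"20"
"fluensulfone","fluensulfone","standard","nematicide",26,160,4160,41.6,"40"
"flumioxazin","flumioxazin","standard","herbicide",4,85366,341464,3414.64,"3500"
"fluroxypyr","fluroxypyr","standard","herbicide",27,2,54,0.54,"1"
"flutriafol","flutriafol","standard","fungicide",9977,1,9977,99.77,"100"
"glufosinate ammonium","glufosinate ammonium","standard","herbicide",6,10,60,0.6,"1"
"glyphosate","glyphosate","standard","herbicide",12,13,156,1.56,"2"
"halosulfuron-methyl","halosulfuron-methyl","standard","herbicide",40,2074,82960,829.6,"830"
"haloxyfop","haloxyfop","standard","herbicide",22,0.04,0.88,0.0088,"<1"
"hexazinone","hexazinone","standard","herbicide",1274,480,611520,6115.2,"6100"
"imazapic","imazapic","standard","herbicide",6,234,1404,14.04,"15"
"imidacloprid (L)","imidacloprid","L","insecticide",1046,2083,2178818,21788.18,"21800"
"imidacloprid (SR)","imidacloprid","SR","insecticide",1046,4167,4358682,43586.82,"43600"
"isoxaflutole","isoxaflutole","standard","herbicide",0.06,326,19.56,0.1956,"<1"
"MCPA","MCPA","standard","herbicide",71,494,35074,350.74,"350"
"metolachlor","metolachlor","standard","herbicide",1170,3757,4395690,43956.9,"44000"
"metribuzin","metribuzin","standard","herbicide",168,600,100800,1008,"1000"
"metsulfuron-methyl","metsulfuron-methyl","standard","herbicide",268,292,78256,782.56,"780"
"MSMA","MSMA","standard","herbicide",1354,5831,7895174,78951.74,"79000"
"paraquat dichloride","paraquat dichloride","standard","herbicide",0.01,148,1.48,0.0148,"<1"
"pendimethalin","pendimethalin","standard","herbicide",0.01,30531,305.31,3.0531,"3"
"permethrin","permethrin","standard","insecticide",0.01,10000,100,1,"1"
"picloram","picloram","standard","herbicide",1871,0.32,598.72,5.9872,"6"
"propiconazole","propiconazole","standard","fungicide",37,3,111,1.11,"1"
"S-metolachlor","S-metolachlor","standard","herbicide",69,7513,518397,5183.97,"5200"
"tebuconazole","tebuconazole","standard","fungicide",242,24,5808,58.08,"58"
"terbuthylazine","terbuthylazine","standard","herbicide",95,875,83125,831.25,"830"
"terbutryn","terbutryn","standard","herbicide",100,3056,305600,3056,"3100"
"triadimenol","triadimenol","standard","fungicide",1345,0.25,336.25,3.3625,"3"
"trichlorfon","trichlorfon","standard","insecticide",6,17647,105882,1058.82,"1100"
"trifloxysulfuron sodium","trifloxysulfuron sodium","standard","herbicide",177,100,17700,177,"180"
"trifluralin","trifluralin","standard","herbicide",0.01,6261,62.61,0.6261,"1"
"trinexapac-ethyl","trinexapac-ethyl","standard","herbicide",0.14,2,0.28,0.0028,"<1"
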