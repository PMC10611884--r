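"name","product_name","rate_units","product_rate_min","product_rate_max","ai_fraction","product_density_kg_L","slow_release_interval_years"
"2,4-D","standard","kg_per_ha",1.21326,2.42653,0.9,1,
"ametryn","standard","kg_per_ha",0.825208,2.50063,0.8,1,
"amicarbazone","standard","kg_per_ha",0.616834,0.934597,0.75,1,
"asulam","standard","kg_per_ha",1.7314,6.92562,0.5,1,
"atrazine","standard","L_per_ha",6.32482,8.43309,0.36,1,
"bifenthrin","standard","kg_per_ha",0.151528,0.151528,0.25,1,
"cadusafos","standard","kg_per_ha",2.21198,4.42396,0.9,1,
"carbofuran","standard","kg_per_ha",1.23214,3.73376,0.8,1,
"chlorothalonil","standard","kg_per_ha",1.45314,2.20173,0.75,1,
"chlorpyrifos","standard","L_per_ha",0.484858,1.93943,0.5,1,
"clothianidin","standard","kg_per_ha",1.07612,1.43483,0.36,1,
"dicamba","standard","kg_per_ha",1.23782,1.23782,0.25,1,
"diquat dibromide","standard","kg_per_ha",0.204901,0.409802,0.9,1,
"diuron","standard","kg_per_ha",0.714777,2.16599,0.8,1,
"fipronil","standard","L_per_ha",0.043224,0.0654909,0.75,1,
"fluazifop-P-butyl","standard","kg_per_ha",0.110408,0.441631,0.5,1,
"fluensulfone","standard","kg_per_ha",3.9867,5.3156,0.36,1,
"flumioxazin","standard","kg_per_ha",1.45193,1.45193,0.25,1,
"fluroxypyr","standard","kg_per_ha",0.34004,0.68008,0.9,1,
"flutriafol","standard","L_per_ha",0.0981829,0.297524,0.8,1,
"glufosinate ammonium","standard","kg_per_ha",0.837025,1.26822,0.75,1,
"glyphosate","standard","kg_per_ha",1.64843,6.59373,0.5,1,
"halosulfuron-methyl","standard","kg_per_ha",0.206662,0.275549,0.36,1,
"haloxyfop","standard","kg_per_ha",0.318296,0.318296,0.25,1,
"hexazinone","standard","L_per_ha",0.296044,0.592087,0.9,1,
"imazapic","standard","kg_per_ha",0.03986,0.120788,0.8,1,
"imidacloprid","L","kg_per_ha",0.220258,0.333725,0.75,1,
"imidacloprid","SR","kg_per_ha",1.00142,4.00566,0.5,1,4
"isoxaflutole","standard","kg_per_ha",0.317249,0.422999,0.36,1,
"MCPA","standard","L_per_ha",4.36068,4.36068,0.25,1,
"metolachlor","standard","kg_per_ha",0.94773,1.89546,0.9,1,
"metribuzin","standard","kg_per_ha",0.636441,1.92861,0.8,1,
"metsulfuron-methyl","standard","kg_per_ha",0.00617364,0.009354,0.75,1,
"MSMA","standard","kg_per_ha",2.36083,9.4433,0.5,1,
"paraquat dichloride","standard","L_per_ha",0.872198,1.16293,0.36,1,
"pendimethalin","standard","kg_per_ha",5.8403,5.8403,0.25,1,
"permethrin","standard","kg_per_ha",0.0565195,0.113039,0.9,1,
"picloram","standard","kg_per_ha",0.0733072,0.222143,0.8,1,
"propiconazole","standard","kg_per_ha",0.0262004,0.0396975,0.75,1,
"S-metolachlor","standard","L_per_ha",0.863508,3.45403,0.5,1,
"tebuconazole","standard","kg_per_ha",0.261647,0.348863,0.36,1,
"terbuthylazine","standard","kg_per_ha",4.18072,4.18072,0.25,1,
"terbutryn","standard","kg_per_ha",0.614665,1.22933,0.9,1,
"triadimenol","standard","kg_per_ha",0.0125051,0.0378942,0.8,1,
"trichlorfon","standard","L_per_ha",0.519724,0.787461,0.75,1,
"trifloxysulfuron sodium","standard","kg_per_ha",0.0186029,0.0744115,0.5,1,
"trifluralin","standard","kg_per_ha",0.0428584,0.0571446,0.36,1,
"trinexapac-ethyl","standard","kg_per_ha",0.746838,0.746838,0.25,1,
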