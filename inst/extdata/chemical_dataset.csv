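name,cas,mw,cdv0_runs,llna_nesil,human_noel,human_loel
Benzalkonium chloride,8001-54-5,424.15,0.350,25.0,-,-
"2,4-Dinitrochlorobenzene",97-00-7,202.55,0.443,13.5,8.8,8.8
Cinnamic aldehyde,104-55-2,132.16,0.524,250,591,775
Citral,5392-40-5,152.23,0.737;1.67,1450,1417,3876
Diethyl maleate,141-05-9,172.18,0.754;1.40,525,1600,-
Dimethyl fumarate,624-49-7,144.13,0.874,87.5,88,-
Methylisothiazolinone,2682-20-4,115.15,0.904,325,15,-
Benzyl Alcohol,100-51-6,108.14,1.37,NS,5905,8858
Chlorpromazine,50-53-3,318.9,1.38,35.0,1150,17241
alpha-Isomethylionone,127-51-5,206.32,1.48;6.51,5450,70860,-
Iodopropynyl butylcarbamate,55406-53-6,281.09,1.61,225,-,-
Isoeugenol,97-54-1,164.21,1.70,325,250,775
"p-Mentha-1,8-dien-7-al",2111-75-3,150.22,1.73;3.38,1010,709,2760
Phenylacetaldehyde,122-78-1,120.15,2.68,750,591,1181
Carvone,6485-40-1,150.22,3.58;7.35,3250,2657,18898
7-Hydroxycitronellal,107-75-5,172.26,5.70,5275,4960,5814
"5-Methyl-2,3-hexanedione",13706-86-0,128.169,8.97,6500,3448,3450
Eugenol,97-53-0,164.21,9.29,2900,5906,-
Ethyl acrylate,140-88-5,100.12,9.47,8188,1600,4000
Cinnamic alcohol,104-54-1,134.17,10.3,5775,2953,4724
Butyl resorcinol,18979-61-8,166.22,10.3;7.55,950,-,-
Farnesol,4602-84-0,222.37,11.5;12.1,1200,2755,6897
Geraniol,106-24-1,154.25,12.7;18.7,4025,11811,-
Imidazolidinyl urea,39236-46-9,388.29,14.9,6000,2000,2000
3-Propylidenephthalide,17369-59-4,174.2,18.8;18.2,925,945,2760
Pentachlorophenol,87-86-5,266.34,20.1,5000,2155,6897
(R)-(+)-Limonene,5989-27-5,136.23,20.2;10.8,13125,10000,-
3-Dimethylaminopropylamine,109-55-7,102.18,25.7,875,-,-
Benzyl salicylate,118-58-1,228.25,37.4,725,17715,-
Linalool,78-70-6,154.25,43.0,8875,14998,-
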