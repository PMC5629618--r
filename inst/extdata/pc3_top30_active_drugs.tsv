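rank	drug_name	score	growth_rate
1	Staurosporine	0.468	-16.375
4	Docetaxel	0.265	18.695
6	Paclitaxel	0.257	1.426
7	Auranofin	0.255	-63.994
12	Bortezomib	0.245	-74.068
13	Cladribine	0.244	2.411
15	Dactinomycin	0.236	-15.905
19	Homoharringtonine	0.226	-42.758
21	Digoxin	0.205	-71.924
30	Etoposide	0.188	43.669
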