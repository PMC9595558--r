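run_library	focal_species	focal_order	n_congeners_in_db
1-1	Papilio machaon	Lepidoptera	14
1-2	Drosophila virilis	Diptera	20
1-3	Drosophila melanogaster	Diptera	20
1-4	Drosophila mojavensis	Diptera	20
1-5	Bactrocera oleae	Diptera	14
1-6	Linepithema humile	Hymenoptera	0
1-7	Bombus terrestris	Hymenoptera	3
1-8	Apis mellifera	Hymenoptera	7
1-9	Acyrthosiphon pisum	Hemiptera	0
2-1	Atta colombica	Hymenoptera	0
2-2	Bemisia tabaci	Hemiptera	1
2-3	Cimex lectularius	Hemiptera	0
2-4	Drosophila melanogaster	Diptera	20
2-5	Drosophila mojavensis	Diptera	20
2-6	Drosophila virilis	Diptera	20
2-7	Drosophila suzukii	Diptera	20
2-8	Linepithema humile	Hymenoptera	0
2-9	Plutella xylostella	Lepidoptera	1
2-10	Solenopsis invicta	Hymenoptera	2
2-11	Vollenhovia emeryi	Hymenoptera	0
2-12	Wasmannia auropunctata	Hymenoptera	0
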