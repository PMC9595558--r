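run_library	species	congeneric	rpir
1-2	Drosophila littoralis	yes	0.0008
1-2	Drosophila incompta	yes	<0.0001
1-5	Bactrocera biguttula	yes	0.0018
1-7	Bombus hypocrita	yes	0.0035
1-7	Bombus waltoni	yes	0.0023
1-7	Bombus ignitus	yes	0.0015
1-8	Apis nigrocincta	yes	0.0011
1-8	Apis florea	yes	0.0006
1-8	Apis laboriosa	yes	0.0002
1-8	Apis nuluensis	yes	0.0002
1-8	Apis andreniformis	yes	<0.0001
1-8	Apis cerana	yes	<0.0001
1-8	Apis dorsata	yes	<0.0001
2-2	Bemisia afer	yes	0.0008
2-2	Barca bicolor	no	0.0004
2-2	Trialeurodes vaporariorum	no	0.0004
2-3	Reduvius tenebrosus	no	0.0009
2-3	Aquatica wuhana	no	0.0001
2-6	Drosophila littoralis	yes	0.0003
2-6	Pachycerina decemlineata	no	0.0002
2-9	Prismognathus prossi	no	0.0002
2-10	Solenopsis richteri	yes	0.0183
2-10	Solenopsis geminata	yes	0.0039
2-10	Myrmica scabrinodis	no	0.0013
2-12	Vespa orientalis	no	0.0028
2-12	Eriogyna pyretorum	no	0.0013
2-12	Pristomyrmex punctatus	no	0.001
2-12	Allocarsidara bakeri	no	0.0001
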