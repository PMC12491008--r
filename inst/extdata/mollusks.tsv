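name	species	omega3_pct_fat	fat_pct	omega3_g_per_g
Argentine shortfin squid	Illex argentinus	52.2	2.0	0.01
Green mussel	Perna viridis	46.4	2.2	0.01
Giant Pacific oyster	Crassostrea gigas	37.9	1.6	0.01
Yesso scallop	Patinopecten yessoensis	42.4	1.2	0.01
Diphos sanguine	Sanguinolaria diphos	26.7	1.6	< 0.01
Bigfin reef squid	Sepioteuthis lessoniana	42.2	0.8	< 0.01
Corbicula clam	Corbicula fluminea	18.4	1.4	< 0.01
Undulating Venus	Paphia undulata	25.7	1.0	< 0.01
Chinese Venus	Cyclina sinensis	24.5	1.0	< 0.01
Inshore squid	Loligo edulis	41.3	0.4	< 0.01
Scallop	Patinopecten yessoensis	37.5	0.4	< 0.01
Cuttlefish	Sepia esculenta	46.4	0.3	< 0.01
Filipino Venus	Ruditapes philippinarum	24.6	0.5	< 0.01
Abalone	Haliotis diversicolor	66.7	0.1	< 0.01
Jackknife clam	Solen strictus	15.7	0.3	< 0.01
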