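name	species	omega3_pct_fat	fat_pct	omega3_g_per_g
Mackerel	Scomber scombrus	20.5	39.4	0.08
Pacific saury	Cololabis saira	21.0	21.8	0.05
Starry butterfish	Stromateus stellatus	18.8	16.3	0.03
Atlantic salmon	Salmo salar	16.7	14.9	0.02
Shishamo	Spirinchus lanceolatus	47.6	4.9	0.02
Antarctic toothfish	Dissostichus eleginoides	8.9	25.5	0.02
Freshwater eel	Anguilla japonica	11.3	19.6	0.02
Croaker	Larimichthys polyactis	22.8	8.0	0.02
Runner	Rachycentron canadum	15.1	7.2	0.02
Silverfish	Trichiurus japonicus	18.3	2.0	0.02
Spotted tangingi	Scomberomorus guttatus	15.1	10.4	0.02
Skipjack	Katsuwonus pelamis	27.7	5.6	0.02
Flounder	Pseudorhombus arsius	9.5	16.1	0.02
Croceine croaker	Larimichthys crocea	17.7	7.8	0.01
Yellow croaker	Larimichthys croceus	15.7	1.6	0.01
East Asian fourfinger threadfin	Eleutheronema rhadinum	17.5	7.2	0.01
Spaniard	Scomberomorus commerson	11.9	10.4	0.01
Thornfish	Terapon jarbua	14.0	8.2	0.01
Chicken grunt	Parapristipoma trilineatum	20.6	5.4	0.01
Rainbow trout	Oncorhynchus mykiss	16.1	6.8	0.01
Japanese butterfish	Psenopsis anomala	12.4	8.7	0.01
Southern mackerel	Scomber australasicus	26.5	4.0	0.01
Sliver stripe round herring	Spratelloides gracilis	75.5	1.3	0.01
Black sea bream	Acanthopagrus schlegelii	10.5	9.0	0.01
Blackspot barracuda	Sphyraena forsteri	13.2	7.1	0.01
Largemouth black bass	Micropterus salmoides	19.0	4.6	0.01
Striped bass	Morone saxatilis	13.9	6.2	0.01
Razor trevally	Mene maculata	29.4	2.9	0.01
Scat	Scatophagus argus	6.5	12.6	0.01
Big head	Hypophthalmichthys nobilis	11.0	7.2	0.01
Yellow fin seabream	Acanthopagrus latus	13.2	6.0	0.01
Purplish amberjack	Seriola dumerili	32.3	2.4	0.01
Tiger grouper	Epinephelus fuscoguttatus	20.7	3.7	0.01
Yellowfin sea bream	Acanthopagrus latus	15.1	4.8	0.01
Rabbitfish	Siganus fuscescens	8.2	8.8	0.01
Round scad	Decapterus macrosoma	28.1	2.4	0.01
Golden thread	Nemipterus virgatus	18.9	3.3	0.01
Japanese jack	Trachurus japonicus	30.9	2.0	0.01
Spottedtail morwong	Cheilodactylus zonatus	18.2	3.4	0.01
Silver sea bream	Rhabdosargus sarba	13.2	4.4	0.01
Silver pomfret	Pampus argenteus	9.9	5.8	0.01
Sand snapper	Lethrinus nebulosus	16.9	3.4	0.01
Lizardfish	Saurida undosquamis	33.1	1.6	0.01
Torpedo scad	Megalaspis cordyla	32.1	1.6	0.01
Tang's snapper	Lipocheilus carnolabrum	13.9	3.7	0.01
Redtail scad	Decapterus kurroides	29.6	1.7	0.01
Ornate surgeonfish	Acanthurus dussumieri	8.1	6.2	0.01
Sea mullet	Mugil cephalas	5.7	8.8	0.01
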