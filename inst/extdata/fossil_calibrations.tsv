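clade	age	type	note
Rhodophyta	1600	Min	a
Bangiophyceae/Florideophyceae	1600	Max
Bangiophyceae/Florideophyceae	1047	Min
Metazoa	833	Max
Ciliophora	740	Min	a
Euglyphidae	736	Min	a
Evosea/Tubulinea	736	Min	a
Tubulinea	736	Max	b
Chlorophyta	700	Min	a
Eumetazoa	636	Max
Deuterostomia	636	Max
Chordata	636	Max
Bilateria	636	Max
Arthropoda	636	Max
Metazoa	635	Min
Eumetazoa	550	Min
Bilateria	550	Min
Mollusca	549	Max
Foraminifera	542	Min	a
Bacillariophyta	541	Max
Embryophyta	540	Max
Mollusca	532	Min
Deuterostomia	515	Min
Chordata	514	Min
Arthropoda	514	Min
Embryophyta	470	Min
Angiosperms/Gymnosperms	470	Max	b
Euglenales/Eutreptiales	450	Min	a
Chytridiomycota	410	Min	a
Tubulinea	405	Min
Ascomycota	400	Min	a
Angiosperms/Gymnosperms	385	Min
Angiosperms	385	Max	b
Basidiomycota	360	Min	a
Amniota	333	Max
Amniota	318	Min
Core dinoflagellates (excl. Noctilucales)	300	Max
Coccolithales/Isochrysidales	260	Max
Core dinoflagellates (excl. Noctilucales)	235	Min
Peridiniales	235	Max	b
Gonyaulacales	235	Max	b
Coccolithales/Isochrysidales	225	Min
Calcidiscaceae/Coccolithaceae	225	Max	b
Peridiniales	210	Min
Gonyaulacales	200	Min
Bacillariophyta	190	Min
Pennales	190	Max	b
Euarchontoglires	165	Max
Angiosperms	130	Min
Eudicotyledons (Tricoplates)	130	Max	b
Eudicotyledons (Tricoplates)	124	Min
Aves sensu stricto	87	Max
Pennales	75	Min
Aves sensu stricto	66	Min
Calcidiscaceae/Coccolithaceae	65	Min
Euarchontoglires	61	Min
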