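taxon	order_label	swainsonine_producer	swnK	swnH2	swnN	swnH1	swnR	swnA	swnT
Pyrenophora seminiperda	Pleosporales	1	1	1	1	1	1	0	0
Periconia macrospinosa	Pleosporales	0	1	1	1	1	1	0	0
Slafractonia leguminicola	Pleosporales	1	1	1	1	1	1	0	1
Alternaria oxytropis	Pleosporales	1	1	1	1	1	1	0	0
Clohesyomyces aquaticus	Pleosporales	0	1	1	1	1	1	0	0
Microsporum canis	Onygenales	0	1	1	1	1	1	1	1
Nannizzia gypsea	Onygenales	1	1	1	1	1	1	1	1
Trichophyton benhamiae	Onygenales	1	1	1	1	1	1	1	1
Trichophyton verrucosum	Onygenales	0	1	1	1	1	1	1	1
Trichophyton violaceum	Onygenales	0	1	1	1	1	1	1	1
Trichophyton soudanense	Onygenales	0	1	1	1	1	1	1	1
Trichophyton rubrum 118892	Onygenales	1	1	1	1	1	1	1	1
Trichophyton tonsurans	Onygenales	0	1	1	1	1	1	1	1
Trichophyton equinum	Onygenales	1	1	1	1	1	1	1	1
Trichophyton interdigitale H6	Onygenales	1	1	1	1	1	1	1	1
Trichophyton mentagrophytes	Onygenales	0	1	1	1	1	0	1	1
Metarhizium acridum CQM	Hypocreales	0	1	1	1	1	1	1	1
Metarhizium anisopliae 53293	Hypocreales	0	1	1	1	1	1	1	1
Metarhizium brunneum 3297	Hypocreales	1	1	1	1	1	1	1	1
Metarhizium guizhouense 977	Hypocreales	1	1	1	1	1	1	1	1
Metarhizium majus 297	Hypocreales	1	1	1	1	1	1	1	1
Metarhizium robertsii 23	Hypocreales	1	1	1	1	1	1	1	1
Fusarium sp. NRRL 66182	Hypocreales	0	1	1	1	1	1	0	0
Chaetothyriaceae sp.	Chaetothyriales	1	1	1	1	1	1	1	0
Xylaria hypoxylon	Xylariales	0	1	1	1	1	1	0	1
Xylaria multiplex	Xylariales	0	1	1	1	1	1	0	1
Xylaria grammica	Xylariales	0	1	1	1	1	1	0	0
Xylaria polymorpha	Xylariales	0	1	1	0	0	1	0	0
Rosellinia necatrix	Xylariales	0	1	1	0	0	1	0	0
Pseudovirgaria hyperparasitica	Capnodiales	0	1	1	1	0	1	1	1
Tothia fuscella	Microthyriales	0	1	1	1	1	1	0	0
Pseudogymnoascus sp.	Leotiomycetes	0	1	1	1	1	1	0	0
Quercus suber	Fagales	0	1	1	1	1	0	0	0
Physcia stellaris	Caliciales	0	1	1	1	1	1	1	0
Rhizodiscinia lignyota	Patellariales	0	1	1	1	1	1	0	0
Talaromyces rugulosus	Eurotiales	0	1	1	1	1	1	1	1
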