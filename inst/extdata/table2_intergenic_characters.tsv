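taxon	taxon_type	character_id	ig_length_nt	overlap	inverted	orf_count	match_classes	blast_status
Pyrenophora seminiperda	A	0	1162	0	0	3	FA	matched
Pyrenophora seminiperda	A	1	40	0	0	0		none
Pyrenophora seminiperda	A	4	606	0	0	2	F	matched
Pyrenophora seminiperda	A	8	3	0	0	0		none
Periconia macrospinosa	A/B	0	913	0	1	4	FA	matched
Periconia macrospinosa	A/B	7	1808	0	0	1		low
Periconia macrospinosa	A/B	12	1993	0	0	6	F	matched
Alternaria oxytropis	A	0	1094	0	0	2	FB	matched
Alternaria oxytropis	A	1	275	0	0	1	A	matched
Alternaria oxytropis	A	4	2007	0	0	1	F	matched
Alternaria oxytropis	A	8	47	0	0	0		none
Clohesyomyces aquaticus	B	1	285	0	0	2	FB	matched
Clohesyomyces aquaticus	B	2	651	0	0	3	F	matched
Clohesyomyces aquaticus	B	4	511	0	0	1	F	matched
Clohesyomyces aquaticus	B	8	45	0	0	0		none
Microsporum canis	B	0	1453	0	0	1	F	matched
Microsporum canis	B	2	348	0	0	1		low
Microsporum canis	B	3	1043	0	0	0		none
Microsporum canis	B	5	212	0	0	0		not_applicable
Microsporum canis	B	9	1267	0	0	1	FA	matched
Microsporum canis	B	11	674	0	0	1	F	matched
Nannizzia gypsea	A	0	1774	0	0	1		low
Nannizzia gypsea	A	2	621	0	0	2	FA	matched
Nannizzia gypsea	A	3	1080	0	0	3	FB	matched
Nannizzia gypsea	A	5	316	0	0	2	B	matched
Nannizzia gypsea	A	9	976	0	0	1	F	matched
Nannizzia gypsea	A	11	823	0	0	3	FB	matched
Trichophyton mentagrophytes	A	0	1353	0	0	1		low
Trichophyton mentagrophytes	A	3	1014	0	0	4	F	matched
Trichophyton mentagrophytes	A	5	306	0	0	0		none
Trichophyton mentagrophytes	A	9	970	0	0	3	F	matched
Trichophyton mentagrophytes	A	11	878	0	0	0		none
Metarhizium acridum	A/B	0	1808	0	0	6	F	matched
Metarhizium acridum	A/B	1	851	0	0	1		low
Metarhizium acridum	A/B	2	451	0	0	2	F	matched
Metarhizium acridum	A/B	3	1317	0	1	1	F	matched
Metarhizium acridum	A/B	5	293	0	1	0		none
Metarhizium acridum	A/B	10	390	0	1	1		low
Chaetothyriaceae sp.	A	0	1989	0	0	3	F	matched
Chaetothyriaceae sp.	A	1	863	0	0	3	FA	matched
Chaetothyriaceae sp.	A	2	320	0	0	1		low
Chaetothyriaceae sp.	A	3	2139	0	0	2	F	matched
Chaetothyriaceae sp.	A	6	163	0	0	0		none
Chaetothyriaceae sp.	A	10	945	0	0	3	B	matched
Xylaria hypoxylon	A/B	0	2581	0	1	3	F	matched
Xylaria hypoxylon	A/B	1	870	0	1	0		none
Xylaria hypoxylon	A/B	2	184	0	1	3	F	matched
Xylaria hypoxylon	A/B	3	1576	0	0	1		low
Xylaria hypoxylon	A/B	5	842	0	0	1	F	matched
Rosellinia necatrix	A/B	0	1664	0	0	2	B	matched
Rosellinia necatrix	A/B	7	1208	0	1	1	A	matched
Pseudovirgaria hyperparasitica	A	0	899	0	0	1	F	matched
Pseudovirgaria hyperparasitica	A	1	154	0	0	0		none
Pseudovirgaria hyperparasitica	A	2	NA	1	0	0		not_applicable
Pseudovirgaria hyperparasitica	A	6	1910	0	0	6	F	matched
Tothia fuscella	A/B	0	437	0	0	3	F	matched
Tothia fuscella	A/B	1	NA	1	1	0		not_applicable
Tothia fuscella	A/B	4	805	0	1	2	F	matched
Tothia fuscella	A/B	6	1646	0	0	3	F	matched
Pseudogymnoascus sp.	A/B	0	1519	0	1	6	FA	matched
Pseudogymnoascus sp.	A/B	1	568	0	0	2	F	matched
Pseudogymnoascus sp.	A/B	4	639	0	0	1	F	matched
Pseudogymnoascus sp.	A/B	7	1958	0	0	3	F	matched
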