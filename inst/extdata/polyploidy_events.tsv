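event	event_name	checked_genome	reference_genome	pindex	printed_nature
1	Brassica-common hexaploidy	B. oleracea	A. thaliana	0.85	Allo
1	Brassica-common hexaploidy	B. rapa	A. thaliana	0.82	Allo
2	B. napus-specific tetraploidy	B. napus	B. rapa	0.78	Allo
2	B. napus-specific tetraploidy	B. napus	B. oleracea	0.76	Allo
3	Arabidopsis tetraploidy 1	A. thaliana	V. vinifera	0.34	
3	Arabidopsis tetraploidy 1	A. lyrata	V. vinifera	0.36	
4	Arabidopsis tetraploidy 2	A. thaliana	V. vinifera	0.41	
4	Arabidopsis tetraploidy 2	A. lyrata	V. vinifera	0.50	
5	Solanaceae-common hexaploidy	S. lycopersicum	C. canephora	0.53	Allo
5	Solanaceae-common hexaploidy	S. tuberosum	C. canephora	0.56	Allo
5	Solanaceae-common hexaploidy	C. annuum	C. canephora	0.50	Allo
5	Solanaceae-common hexaploidy	C. annuum	V. vinifera	0.48	Allo
5	Solanaceae-common hexaploidy	S. melongena	C. canephora	0.47	Allo
6	Gossypium-common decaploidy	G. raimondii	T. cacao	0.47	Allo
6	Gossypium-common decaploidy	G. raimondii	V. vinifera	0.57	Allo
6	Gossypium-common decaploidy	G. arboreum	T. cacao	0.42	Allo
6	Gossypium-common decaploidy	G. arboreum	V. vinifera	0.51	Allo
7	Gossypium tetraploidy	G. hirsutum	G. raimondii	0.70	Allo
8	Fabaceae-common tetraploidy	M. truncatula	V. vinifera	0.39	Allo
8	Fabaceae-common tetraploidy	V. radiata	V. vinifera	0.45	Allo
8	Fabaceae-common tetraploidy	V. angularis	V. vinifera	0.49	Allo
8	Fabaceae-common tetraploidy	C. arietium	V. vinifera	0.42	Allo
8	Fabaceae-common tetraploidy	P. vulgaris	V. vinifera	0.42	Allo
8	Fabaceae-common tetraploidy	L. japonicus	V. vinifera	0.50	Allo
8	Fabaceae-common tetraploidy	C. cajan	V. vinifera	0.36	Allo
8	Fabaceae-common tetraploidy	A. ipaensis	V. vinifera	0.48	Allo
8	Fabaceae-common tetraploidy	A. duranensis	V. vinifera	0.51	Allo
9	Soybean-specific tetraploidy	G. max	M. truncatula	0.17	Auto
10	Cucurbitaceae-common tetraploidy	C. lanatus	V. vinifera	0.38	Allo
10	Cucurbitaceae-common tetraploidy	C. sativus	V. vinifera	0.56	Allo
10	Cucurbitaceae-common tetraploidy	C. melo	V. vinifera	0.67	Allo
11	Apple-specific autotetraploidy	M. domestica	P. persica	0.22	Auto
11	Apple-specific autotetraploidy	M. domestica	P. mume	0.22	Auto
12	Poplar-specific autotetraploidy	P. trichocarpa	P. persica	0.26	Auto
13	Major eudicot-common hexaploidy	V. vinifera	V. vinifera	0.79	Allo
14	Grass-common tetraploidy	O. sativa	A. comosus	0.43	Allo
14	Grass-common tetraploidy	S. bicolor	A. comosus	0.41	Allo
14	Grass-common tetraploidy	S. italica	A. comosus	0.44	Allo
14	Grass-common tetraploidy	B. distachyon	A. comosus	0.39	Allo
15	Zea-specific tetraploidy	Z. mays	O. sativa	0.84	Allo
15	Zea-specific tetraploidy	Z. mays	S. italica	0.69	Allo
15	Zea-specific tetraploidy	Z. mays	S. bicolor	0.71	Allo
16	Triticum-specific hexaploidy	T. aestivum	A. tauschii	0.42	Allo
16	Triticum-specific hexaploidy	T. aestivum	T. urartu	0.43	Allo
16	Triticum-specific hexaploidy	T. aestivum-1	H. vulgare	0.75	Allo
16	Triticum-specific hexaploidy	T. aestivum-2	H. vulgare	0.52	Allo
17	Ananas tetraploidy	A. comosus	E. guineensis	0.39	Allo
17	Ananas tetraploidy	A. comosus	S. polyrhiza	0.44	Allo
17	Ananas tetraploidy	A. comosus	V. vinifera	0.42	Allo
18	Elaeis-specific tetraploidy	E. guineensis	A. comosus	0.58	Allo
18	Elaeis-specific tetraploidy	E. guineensis	S. polyrhiza	0.50	Allo
19	Commelinids-common tetraploidy	E. guineensis	S. polyrhiza	0.50	Allo
20	S. polyrhiza tetraploidy 1	S. polyrhiza	V. vinifera	0.47	Allo
21	S. polyrhiza tetraploidy 2	S. polyrhiza	V. vinifera	0.44	Allo
22	Musa tetraploidy 1	M. acuminata	E. guineensis	0.37	Allo
23	Musa tetraploidy 2	M. acuminata	E. guineensis	0.35	Allo
24	Musa tetraploidy 3	M. acuminata	E. guineensis	0.44	Allo
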