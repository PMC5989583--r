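serial	species	strain	accession	chromosome_bp	status	gc_mol_pct	genotype	pgc	group	colour
1	Sphingopyxis alaskensis	RB2256	CP000356	3345170	complete	65.50	E,B,I,Y,Z,G	FALSE	I	yellow to beige
2	Sphingopyxis macrogoltabida	EY-1	CP012700	4757879	complete	64.90	E,B,I,Y,Z,G	FALSE	I	unknown
3	Sphingopyxis fribergensis	Kp5.2	CP009122	4993584	complete	63.90	E,B,I,Y,Z,G	FALSE	I	yellow
4	Sphingomonas sanxanigenens	DSM 19645	CP006644	6205897	complete	66.80	E,B,I,Y,Z,G	TRUE	I	colourless/white
5	Sphingorhabdus sp.	M41	CP014545	3339521	complete	56.70	E,B,I,Y,Z,G	FALSE	I	colourless/white
6	Sphingopyxis sp.	113P3	CP009452	4420776	complete	64.00	E,B,I,Y,Z,G	FALSE	I	yellowish brown
7	Sphingopyxis terrae	NBRC 15098	CP013342	3979087	complete	64.60	E,B,I,Y,Z,G	FALSE	I	light or deep-yellow
8	Sphingobium sp.	SYK-6	NC_015976	4199332	complete	65.60	E,B,I,Y,Z,G	FALSE	I	yellow
9	Sphingomonas hengshuiensis	WHSC-8	CP010836	5191536	complete	66.70	E,B,I,Y,Z,G	TRUE	I	yellow
10	Sphingomonas sp.	Root241	NZ_LMIV00000000	4212322	draft	66.00	E,B,I,Y,Z,G	FALSE	I	unknown
11	Sphingomonas sp.	ATCC 31555	NZ_ALBQ00000000	4046117	draft	65.90	E,B,I,Y,Z,G,W	FALSE	II	red
12	Sphingomonas paucimobilis	NBRC 13935	NZ_BBJS00000000	4327402	draft	65.70	E,B,I,Y,Z,G	FALSE	I	yellow
13	Sphingomonas astaxanthinifaciens	DSM 22298	NZ_JONN00000000	2533034	draft	68.40	E,B,I,Y,Z,W,X	TRUE	III	red
14	Sphingobium chlorophenolicum	L-1	CP002798	3080818	complete	63.90	E,B,I,Y,Z,G	FALSE	I	yellow
15	Sphingobium sp.	MI1205	CP005188	3351250	complete	62.30	E,B,I,Y,Z,G	FALSE	I	brownish-yellow
16	Sphingobium sp.	EP60837	CP015986	2669660	complete	62.40	E,B,I,Y,Z,G	FALSE	I	colourless/white
17	Sphingobium sp.	YBL2	CP010954	4766421	complete	64.80	E,B,I,Y,Z,G	FALSE	I	yellow
18	Novosphingobium aromaticivorans	DSM 12444	CP000248	3561584	complete	65.20	E,B,I,Y,Z,G	FALSE	I	yellow
19	Citromicrobium sp.	JL477	CP011344	3258499	complete	65.00	E,B,I,Y,Z,G	TRUE	I	yellow
20	Altererythrobacter dongtanensis	KCTC 22672	CP016591	3009495	complete	65.80	E,B,I,Y,Z,G	FALSE	I	yellow
21	Altererythrobacter namhicola	JCM 16345	CP016545	2591679	complete	65.00	E,B,I,Y,Z,G,W	FALSE	II	orange
22	Altererythrobacter epoxidivorans	CGMCC 1.7731	CP012669	2786256	complete	61.50	E,B,I,Y,Z,G	FALSE	I	yellow
23	Altererythrobacter atlanticus	26DY36	CP011452	3386291	complete	61.90	E,B,I,Y,Z,G	FALSE	I	yellow
24	Altererythrobacter ishigakiensis	NBRC 107699	CP015963	2673978	complete	56.90	E,B,I,Y,Z,G,W	TRUE	II	orange-red
25	Erythrobacter litoralis	HTCC2594	CP000157	3052398	complete	63.10	E,B,I,Y,Z,G,W	FALSE	II	pink
26	Erythrobacter atlanticus	s21-N3	CP011310	3012400	complete	58.20	E,B,I,Y,Z,G	FALSE	I	yellow-brown
27	Sphingobium yanoikuyae	ATCC 51230	NZ_AGZU00000000	5500358	draft	64.40	E,B,I,Y,Z,G	FALSE	I	creamy white
28	Novosphingobium sp.	PP1Y	FR856862	3911486	complete	63.70	E,B,I,Y,Z,G	FALSE	I	yellow
29	Novosphingobium pentaromativorans	US6-1	CP009291	3979506	complete	63.50	E,B,I,Y,Z,G	FALSE	I	yellow
30	Porphyrobacter neustonensis	DSM 9434	CP016033	3090363	complete	65.30	E,B,I,Y,Z,G,W	TRUE	II	orange
31	Sphingomonas sp.	NIC1	CP015521	3408545	complete	67.40	E,B,I,Y,Z,G	FALSE	I	unknown
32	Sphingomonas melonis	TY	NZ_LQCK00000000	4100783	draft	67.10	E,B,I,Y,Z,G	FALSE	I	yellow
33	Altererythrobacter marensis	KCTC 22370	CP011805	2885033	complete	64.70	E,B,I,Y,Z,G	FALSE	I	yellow
34	Croceicoccus naphthovorans	PQ-2	CP011770	3543806	complete	62.60	E,B,I,Y,Z,G	FALSE	I	yellow
35	Sphingomonas taxi	ATCC 55669	CP009571	3859099	complete	68.00	E,B,I,Y,Z,G,W	FALSE	II	yellow to orange
36	Sphingomonas sp.	RIT328	NZ_JFYV00000000	4343511	draft	68.30	E,B,I,Y,Z,G,W	FALSE	II	unknown
37	Sphingobium japonicum	UT26S	NC_014006	3514822	complete	64.80	E,B,I,Y,Z,G	FALSE	I	yellow
38	Sphingomonas sp.	MM-1	CP004036	4054833	complete	67.20	E,I,Y	FALSE	IV	colourless/white
39	Sphingobium baderi	DE-13	CP013264	4107398	complete	62.40	E,I	FALSE	IV	colourless/white
40	Sphingomonas wittichii	RW1	CP000699	5382261	complete	68.40	E,Y	FALSE	IV	greyish-white
41	Sphingopyxis granuli	TFA	CP012199	4679853	complete	66.20	E	FALSE	IV	yellowish
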