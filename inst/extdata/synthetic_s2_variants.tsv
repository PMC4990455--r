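# Synthetic stand-in for a curated animal-disease SAV table
# (S2-shaped: 117 SAVs over 99 sequences, dog 39% / cattle 21%,
#  110 plain + 7 '+1'-shift matches). Generated by
# data-raw/make_fixtures.R; sequences in synthetic_s2_sequences.fasta.
gene_symbol	taxon_id	protein_ref	variant	label	source
SYNG001	9615	SYNP001	G10D	synthetic disorder 01	synthetic
SYNG001	9615	SYNP001	F9Y	synthetic disorder 01	synthetic
SYNG002	9615	SYNP002	I45F	synthetic disorder 02	synthetic
SYNG002	9615	SYNP002	P34T	synthetic disorder 02	synthetic
SYNG003	9615	SYNP003	M27L	synthetic disorder 03	synthetic
SYNG003	9615	SYNP003	V25F	synthetic disorder 03	synthetic
SYNG004	9615	SYNP004	E48G	synthetic disorder 04	synthetic
SYNG004	9615	SYNP004	G26E	synthetic disorder 04	synthetic
SYNG005	9615	SYNP005	R29L	synthetic disorder 05	synthetic
SYNG005	9615	SYNP005	V56L	synthetic disorder 05	synthetic
SYNG006	9615	SYNP006	H35D	synthetic disorder 06	synthetic
SYNG006	9615	SYNP006	Y15H	synthetic disorder 06	synthetic
SYNG007	9615	SYNP007	C65S	synthetic disorder 07	synthetic
SYNG007	9615	SYNP007	T48P	synthetic disorder 07	synthetic
SYNG008	9615	SYNP008	L33W	synthetic disorder 08	synthetic
SYNG008	9615	SYNP008	K52E	synthetic disorder 08	synthetic
SYNG009	9615	SYNP009	P11S	synthetic disorder 09	synthetic
SYNG009	9615	SYNP009	G32V	synthetic disorder 09	synthetic
SYNG010	9615	SYNP010	K30M	synthetic disorder 10	synthetic
SYNG010	9615	SYNP010	H23P	synthetic disorder 10	synthetic
SYNG011	9913	SYNP011	Q48K	synthetic disorder 11	synthetic
SYNG011	9913	SYNP011	N56Y	synthetic disorder 11	synthetic
SYNG012	9913	SYNP012	P47A	synthetic disorder 12	synthetic
SYNG012	9913	SYNP012	A45G	synthetic disorder 12	synthetic
SYNG013	9913	SYNP013	E6A	synthetic disorder 13	synthetic
SYNG013	9913	SYNP013	D50V	synthetic disorder 13	synthetic
SYNG014	9913	SYNP014	S40T	synthetic disorder 14	synthetic
SYNG014	9913	SYNP014	M64V	synthetic disorder 14	synthetic
SYNG015	9913	SYNP015	D14E	synthetic disorder 15	synthetic
SYNG015	9913	SYNP015	T10R	synthetic disorder 15	synthetic
SYNG016	9796	SYNP016	E55V	synthetic disorder 16	synthetic
SYNG016	9796	SYNP016	K37T	synthetic disorder 16	synthetic
SYNG017	9796	SYNP017	Y33F	synthetic disorder 17	synthetic
SYNG017	9796	SYNP017	T11M	synthetic disorder 17	synthetic
SYNG018	9796	SYNP018	Y40D	synthetic disorder 18	synthetic
SYNG018	9796	SYNP018	K14Q	synthetic disorder 18	synthetic
SYNG019	9615	SYNP019	P51H	synthetic disorder 19	synthetic
SYNG020	9615	SYNP020	I40L	synthetic disorder 20	synthetic
SYNG021	9615	SYNP021	I62F	synthetic disorder 21	synthetic
SYNG022	9615	SYNP022	N59Y	synthetic disorder 22	synthetic
SYNG023	9615	SYNP023	G16A	synthetic disorder 23	synthetic
SYNG024	9615	SYNP024	C17S	synthetic disorder 24	synthetic
SYNG025	9615	SYNP025	G67W	synthetic disorder 25	synthetic
SYNG026	9615	SYNP026	Y23H	synthetic disorder 26	synthetic
SYNG027	9615	SYNP027	W9G	synthetic disorder 27	synthetic
SYNG028	9615	SYNP028	W42L	synthetic disorder 28	synthetic
SYNG029	9615	SYNP029	L35M	synthetic disorder 29	synthetic
SYNG030	9615	SYNP030	I41T	synthetic disorder 30	synthetic
SYNG031	9615	SYNP031	A20G	synthetic disorder 31	synthetic
SYNG032	9615	SYNP032	M29I	synthetic disorder 32	synthetic
SYNG033	9615	SYNP033	F56C	synthetic disorder 33	synthetic
SYNG034	9615	SYNP034	F48V	synthetic disorder 34	synthetic
SYNG035	9615	SYNP035	P53H	synthetic disorder 35	synthetic
SYNG036	9615	SYNP036	I31T	synthetic disorder 36	synthetic
SYNG037	9615	SYNP037	V46F	synthetic disorder 37	synthetic
SYNG038	9615	SYNP038	F62C	synthetic disorder 38	synthetic
SYNG039	9615	SYNP039	L41S	synthetic disorder 39	synthetic
SYNG040	9615	SYNP040	D54Y	synthetic disorder 40	synthetic
SYNG041	9615	SYNP041	M40L	synthetic disorder 41	synthetic
SYNG042	9615	SYNP042	N5I	synthetic disorder 42	synthetic
SYNG043	9615	SYNP043	R42G	synthetic disorder 43	synthetic
SYNG044	9615	SYNP044	K4T	synthetic disorder 44	synthetic
SYNG045	9913	SYNP045	F26S	synthetic disorder 45	synthetic
SYNG046	9913	SYNP046	L63H	synthetic disorder 46	synthetic
SYNG047	9913	SYNP047	P4Q	synthetic disorder 47	synthetic
SYNG048	9913	SYNP048	P52R	synthetic disorder 48	synthetic
SYNG049	9913	SYNP049	H18L	synthetic disorder 49	synthetic
SYNG050	9913	SYNP050	R13I	synthetic disorder 50	synthetic
SYNG051	9913	SYNP051	H23N	synthetic disorder 51	synthetic
SYNG052	9913	SYNP052	K61T	synthetic disorder 52	synthetic
SYNG053	9913	SYNP053	W42G	synthetic disorder 53	synthetic
SYNG054	9913	SYNP054	D28G	synthetic disorder 54	synthetic
SYNG055	9913	SYNP055	H38P	synthetic disorder 55	synthetic
SYNG056	9913	SYNP056	S40F	synthetic disorder 56	synthetic
SYNG057	9913	SYNP057	S48R	synthetic disorder 57	synthetic
SYNG058	9913	SYNP058	Q41R	synthetic disorder 58	synthetic
SYNG059	9913	SYNP059	F39S	synthetic disorder 59	synthetic
SYNG060	9796	SYNP060	S45L	synthetic disorder 60	synthetic
SYNG061	9796	SYNP061	H49P	synthetic disorder 61	synthetic
SYNG062	9796	SYNP062	N53T	synthetic disorder 62	synthetic
SYNG063	9796	SYNP063	K19T	synthetic disorder 63	synthetic
SYNG064	9796	SYNP064	I62N	synthetic disorder 64	synthetic
SYNG065	9796	SYNP065	L18Q	synthetic disorder 65	synthetic
SYNG066	9685	SYNP066	I55M	synthetic disorder 66	synthetic
SYNG067	9685	SYNP067	D61N	synthetic disorder 67	synthetic
SYNG068	9685	SYNP068	N48H	synthetic disorder 68	synthetic
SYNG069	9685	SYNP069	T28A	synthetic disorder 69	synthetic
SYNG070	9685	SYNP070	N7K	synthetic disorder 70	synthetic
SYNG071	9685	SYNP071	K50I	synthetic disorder 71	synthetic
SYNG072	9685	SYNP072	G69A	synthetic disorder 72	synthetic
SYNG073	9685	SYNP073	L24S	synthetic disorder 73	synthetic
SYNG074	9685	SYNP074	K51E	synthetic disorder 74	synthetic
SYNG075	9685	SYNP075	F22C	synthetic disorder 75	synthetic
SYNG076	9940	SYNP076	S24N	synthetic disorder 76	synthetic
SYNG077	9940	SYNP077	M40I	synthetic disorder 77	synthetic
SYNG078	9940	SYNP078	M63T	synthetic disorder 78	synthetic
SYNG079	9940	SYNP079	C43S	synthetic disorder 79	synthetic
SYNG080	9940	SYNP080	N21D	synthetic disorder 80	synthetic
SYNG081	9940	SYNP081	E45K	synthetic disorder 81	synthetic
SYNG082	9940	SYNP082	D28V	synthetic disorder 82	synthetic
SYNG083	9940	SYNP083	V23L	synthetic disorder 83	synthetic
SYNG084	9940	SYNP084	C26G	synthetic disorder 84	synthetic
SYNG085	9823	SYNP085	F49Y	synthetic disorder 85	synthetic
SYNG086	9823	SYNP086	S24Y	synthetic disorder 86	synthetic
SYNG087	9823	SYNP087	A15P	synthetic disorder 87	synthetic
SYNG088	9823	SYNP088	F25C	synthetic disorder 88	synthetic
SYNG089	9823	SYNP089	D36Y	synthetic disorder 89	synthetic
SYNG090	9823	SYNP090	Y3C	synthetic disorder 90	synthetic
SYNG091	9823	SYNP091	L48F	synthetic disorder 91	synthetic
SYNG092	9823	SYNP092	M68L	synthetic disorder 92	synthetic
SYNG093	9031	SYNP093	P8H	synthetic disorder 93	synthetic
SYNG094	9031	SYNP094	V10G	synthetic disorder 94	synthetic
SYNG095	9031	SYNP095	I20M	synthetic disorder 95	synthetic
SYNG096	9031	SYNP096	R30G	synthetic disorder 96	synthetic
SYNG097	9031	SYNP097	N17T	synthetic disorder 97	synthetic
SYNG098	9031	SYNP098	L32R	synthetic disorder 98	synthetic
SYNG099	9031	SYNP099	D9N	synthetic disorder 99	synthetic
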