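symbiont_tip	species	host	locality	collectors	collection_date	accession_co1	accession_ef1a
EN01	E. binotata	Sideroxylon lycioides	Moulton, AL	C.H. Dietrich	26-May-2004	KX791061	KX791122
EN02	E. binotata	Sideroxylon lanuginosum	Van Buren, MO	R.B. Cocroft	30-Apr-2006	KX791062	KX791123
EN03	E. binotata	Sideroxylon lanuginosum	Austin, TX	F.W. Stearns	01-Apr-2007	KX791063	KX791124
EN04	E. binotata	Carya	Mooresville, IN	R.L. Snyder	11-Jun-2004	KX791064	KX791125
EN05	E. binotata	Carya	Cloud Crossing, LA	C.P. Lin	27-Apr-2003	KX791065	KX791126
EN06	E. binotata	Celastrus scandens	Columbia, MO	R.B. Cocroft	01-Jul-2002	KX791066	KX791127
EN07	E. binotata	Celastrus scandens	Ithaca, NY	T.K. Wood & C.P. Lin	06-Jul-2002	KX791067	KX791128
EN08	E. binotata	Celastrus scandens	Stone Valley, PA	R.B. Cocroft & C.P. Lin	04-Jun-2003	KX791068	KX791129
EN09	E. binotata	Cercis canadensis	Chinnabee, AL	C.P. Lin	01-May-2003	KX791069	KX791130
EN10	E. binotata	Cercis canadensis	Rutledge, GA	R.B. Cocroft & C.P. Lin	07-May-2003	KX791070	KX791131
EN11	E. binotata	Cercis canadensis	Effingham, IL	C.P. Lin	21-May-2003	KX791071	KX791132
EN12	E. binotata	Cercis canadensis	Woodmont, MD	R.B. Cocroft & C.P. Lin	07-Jun-2003	KX791072	KX791133
EN13	E. binotata	Cercis canadensis	Columbia, MO	R.B. Cocroft	01-Jun-2002	KX791073	KX791134
EN14	E. binotata	Cercis canadensis	Tupelo, MS	C.P. Lin	29-Apr-2003	KX791074	KX791135
EN15	E. binotata	Cercis canadensis	New Buffalo, PA	R.L. Snyder & N. Cai	09-Jul-2002	KX791075	KX791136
EN16	E. binotata	Cercis canadensis	Parksville, TN	R.B. Cocroft & C.P. Lin	03-May-2003	KX791076	KX791137
EN17	E. binotata	Cercis canadensis	Grafton, WV	R.B. Cocroft & C.P. Lin	06-Jun-2003	KX791077	KX791138
EN18	E. binotata	Dirca palustris	Bloomingdale, IN	R.E. Hunt	15-Aug-2004	KX791078	KX791139
EN19	E. binotata	Dirca palustris	White Lake, ON	R. Lee	01-Jul-2004	KX791079	KX791140
EN20	Enchenopa sp.	Unknown	Guatemala City, Guatemala	C.P. Lin	20-Dec-1999	KX791080	KX791141
EN21	Enchenopa sp.	Unknown	Gracias, Honduras	C.P. Lin & R.L. Snyder	22-Jul-2001	KX791081	KX791142
EN22	Enchenopa sp.	Unknown	Juticalpa, Honduras	C.P. Lin & R.L. Snyder	24-Jul-2001	KX791082	KX791143
EN23	Enchenopa sp.	Unknown	Lucerna, Honduras	C.P. Lin & R.L. Snyder	21-Jul-2001	KX791083	KX791144
EN24	Enchenopa sp.	Unknown	La Union, Honduras	C.P. Lin & R.L. Snyder	25-Jul-2001	KX791084	KX791145
EN25	Enchenopa sp.	Unknown	Bambito, Panama	T.K. Wood et al.	18-Jan-2000	KX791085	KX791146
EN26	Enchenopa sp.	Composite	Boquete, Panama	T.K. Wood & R.B. Cocroft	06-Mar-1998	KX791086	KX791147
EN27	Enchenopa sp.	Unknown	Panama	T.K. Wood et al.	01-Jan-2000	KX791087	KX791148
EN28	Enchenopa sp.	Diphysa robinoides	Pedasi, Panama	R.B. Cocroft	13-Feb-2000	KX791088	KX791149
EN29	Enchenopa sp.	Unknown	Gamboa, Panama	T.K. Wood et al.	21-Jan-2000	KX791089	KX791150
EN30	Enchenopa sp.	Unknown	La Union, Mexico	G. Moya Raygoza	24-Oct-2001	KX791090	KX791151
EN31	Enchenopa sp.	Unknown	La Huerta, Mexico	S.H. McKamey	16-Oct-2001	KX791091	KX791152
EN32	Enchenopa sp.	Unknown	Veracruz, Mexico	R.B. Cocroft & C.P. Lin	2007	KX791092	KX791153
EN33	Enchenopa sp.	Unknown	Veracruz, Mexico	R.B. Cocroft & C.P. Lin	2007	KX791093	KX791154
EN34	Enchenopa sp.	Unknown	Tegucigalpa, Honduras	C.P. Lin & R.L. Snyder	24-Jul-2001	KX791094	KX791155
EN35	Enchenopa sp.	Unknown	Trinidad, Honduras	C.P. Lin & R.L. Snyder	29-Jul-2001	KX791095	KX791156
EN36	Enchenopa sp.	Unknown	Chiriqui Grande, Panama	T.K. Wood & R.B. Cocroft	05-Mar-1998	KX791096	KX791157
EN37	E. binotata	Juglans cinerea	Bangor, NY	T.K. Wood	30-Aug-1997	KX791097	KX791158
EN38	E. binotata	Juglans cinerea	Ithaca, NY	T.K. Wood	16-Jun-1996	KX791098	KX791159
EN39	E. binotata	Juglans nigra	Woodmont, MD	R.B. Cocroft & C.P. Lin	07-Jun-2003	KX791099	KX791160
EN40	E. binotata	Juglans nigra	Columbia, MO	R.B. Cocroft	01-Jul-2002	KX791100	KX791161
EN41	E. binotata	Liriodendron tulipifera	Ithaca, NY	C.P. Lin	16-Jul-2002	KX791101	KX791162
EN42	E. binotata	Liriodendron tulipifera	Oxford, OH	R.L. Snyder	14-Jun-2004	KX791102	KX791163
EN43	E. binotata	Liriodendron tulipifera	Harveysburg, OH	R.L. Snyder	14-Jun-2004	KX791103	KX791164
EN44	E. binotata	Ptelea trifoliata	Yorkville, IL	R.L. Snyder	03-Jun-2004	KX791104	KX791165
EN45	E. binotata	Ptelea trifoliata		R.E. Hunt	01-Jun-2002	KX791105	KX791166
EN46	E. binotata	Ptelea trifoliata	Columbia, MO	R.B. Cocroft	01-Jun-2002	KX791106	KX791167
EN47	E. binotata	Robinia pseudoacacia	Woodmont, MD	R.B. Cocroft & C.P. Lin	07-Jun-2003	KX791107	KX791168
EN48	E. binotata	Robinia pseudoacacia	Columbia, MO	R.B. Cocroft	01-Jul-2002	KX791108	KX791169
EN49	E. binotata	Robinia pseudoacacia	Ithaca, NY	T.K. Wood & C.P. Lin	06-Jul-2002	KX791109	KX791170
EN50	E. binotata	Robinia pseudoacacia	Stone Valley, PA	R.B. Cocroft & C.P. Lin	04-Jun-2003	KX791110	KX791171
EN51	E. binotata	Viburnum cassinoides	Cherry Lane, NC	R.L. Snyder & N. Cai	05-Jun-2003	KX791111	KX791172
EN52	E. binotata	Viburnum cassinoides	Davis, WV	R.B. Cocroft & C.P. Lin	06-Jun-2003	KX791112	KX791173
EN53	E. binotata	Viburnum lentago	Bernheim, KY	R.E. Hunt	01-Jun-2002	KX791113	KX791174
EN54	E. binotata	Viburnum lentago	Ridgeway, PA	R.B. Cocroft & C.P. Lin	05-Jun-2003	KX791114	KX791175
EN55	E. binotata	Viburnum prunifolium	Columbia, MO	R.B. Cocroft	27-Jun-2002	KX791115	KX791176
EN56	E. binotata	Viburnum prunifolium	Stone Valley, PA	R.B. Cocroft & C.P. Lin	04-Jun-2003	KX791116	KX791177
EN57	E. binotata	Viburnum prunifolium	Amherst, VA	R.L. Snyder & N. Cai	06-Jun-2003	KX791117	KX791178
EN58	E. binotata	Viburnum rufidulum	Rutledge, GA	R.B. Cocroft & C.P. Lin	07-May-2003	KX791118	KX791179
EN59	E. binotata	Viburnum rufidulum	Columbia, MO	R.B. Cocroft & C.P. Lin	01-Jun-2003	KX791119	KX791180
EN60	E. binotata	Viburnum rufidulum	Greenville, SC	C.P. Lin	08-May-2003	KX791120	KX791181
EN61	E. binotata	Viburnum rufidulum	Nashville, TN	R.B. Cocroft & C.P. Lin	02-May-2003	KX791121	KX791182
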