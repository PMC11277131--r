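locality_id	name	lat	lon
Gnishik	Armenia, Vayots Dzor, Gnishik	39.673	45.291
Sevan_Lake	Armenia, Gegharkunik, Sevan Lake (Artanish south slopes)	40.468	45.306
Sevan_Lake_Madina	Armenia, Gegharkunik, Madina	40.472	45.257
Sevan_Lake_Artanish	Armenia, Gegharkunik, Artanish mnt.	40.472	45.317
Vayots_Dzor	Armenia, Vayots Dzor, Hermon	39.902	45.442
Jirgatol	Tajikistan, Jirgatol	39.220	71.100
Ja_Joor_pass	Armenia, Ja Joor pass	39.050	46.250
Shvanidzor	Armenia, Syunik, Shvanidzor (Gyumarants)	39.003	46.380
Gyumarants	Armenia, Syunik, Gyumarants	39.003	46.380
Keleybar_Makidi	Iran, East Azerbaijan, Makidi (W of Kaleybar)	38.850	46.890
Varzagan	Iran, East Azerbaijan, Varzagan	38.510	46.650
Aragats	Armenia, Aragatsotn, Aragats	40.450	44.200
Megri_Lichk	Armenia, Syunik, Megri, Lichk	38.860	46.240
Khosrov	Armenia, Ararat, Khosrov reserve	39.960	44.870
Vohkchaberd	Armenia, Ararat, Vohkchaberd	40.130	44.640
Garny	Armenia, Kotayk, Garny	40.120	44.730
Geghadir	Armenia, Kotayk, Geghadir	40.130	44.600
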