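accession_id	pi_number	rodale_accession	origin_country	collection_site	elevation_m	status	cultivar_name	acquisition_mode	acquisition_year	source_table	molecular
PI 273732	PI 273732	867	Russia	Rostov	NA	cultivated	Rostovsky 31	unknown	NA	table1	TRUE
PI 286118	PI 286118	869	Denmark	botanical garden	NA	uncertain	NA	unknown	NA	table1	TRUE
PI 314054	PI 314054	873	Russia	Rostov	NA	uncertain	NA	unknown	NA	table1	TRUE
PI 315353	PI 315353	875	Russia	Voronezh region	NA	uncertain	NA	unknown	NA	table1	TRUE
PI 315355	PI 315355	877	Russia	Stavropol region	NA	wild	NA	unknown	NA	table1	TRUE
PI 316122	PI 316122	878	Former USSR	NA	NA	uncertain	NA	unknown	NA	table1	TRUE
PI 326209	PI 326209	833	Former USSR	Atai region	NA	wild	NA	unknown	NA	table1	FALSE
PI 401201	PI 401201	785	Iran	SE of Khorranabad	1600	wild	NA	unknown	NA	table1	FALSE
PI 440004	PI 440004	793	Russia	NA	NA	cultivated	Rostov 31	unknown	NA	table1	TRUE
PI 440008	PI 440008	797	Russia	SE of Stavropol	400	wild	NA	unknown	NA	table1	FALSE
PI 440011	PI 440011	800	Russia	near Svetlograd	250	wild	NA	unknown	NA	table1	TRUE
PI 440014	PI 440014	898	Russia	SE of Svetlograd	NA	wild	NA	unknown	NA	table1	FALSE
PI 440015	PI 440015	899	Russia	SE of Svetlograd	300	cultivated	Rostov 31	unknown	NA	table1	TRUE
PI 440017	PI 440017	901	Russia	SE of Svetlograd	300	wild	NA	unknown	NA	table1	TRUE
PI 440028	PI 440028	836	Russia	SE of Stavropol	500	unknown	NA	unknown	NA	table1	FALSE
PI 440029	PI 440029	837	Russia	E of Stavropol	600	wild	NA	unknown	NA	table1	FALSE
PI 440031	PI 440031	839	Russia	E of Stavropol	400	wild	NA	unknown	NA	table1	FALSE
PI 440038	PI 440038	918	Kazakhstan	SE of Dzhambul	1080	wild	NA	unknown	NA	table1	FALSE
PI 440039	PI 440039	846	Kazakhstan	SE of Dzhambul	900	wild	NA	unknown	NA	table1	FALSE
RI 31	NA	31	NA	NA	NA	unknown	NA	unknown	NA	table1	FALSE
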