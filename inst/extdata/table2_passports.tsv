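accession_id	pi_number	rodale_accession	origin_country	collection_site	elevation_m	status	cultivar_name	acquisition_mode	acquisition_year	source_table	molecular
PI 210992	PI 210992	863	Afghanistan	Herat Province	NA	wild	NA	unknown	NA	table2	TRUE
PI 273733	PI 273733	868	Russia	Kursk Oblast	NA	uncertain	NA	unknown	NA	table2	TRUE
PI 297876	PI 297876	822	Russia	NA	NA	uncertain	NA	unknown	NA	table2	TRUE
PI 314192	PI 314192	827	Uzbekistan	E Tashkent	NA	wild	NA	unknown	NA	table2	TRUE
PI 315065	PI 315065	830	Former Soviet Union	NA	NA	uncertain	NA	unknown	NA	table2	TRUE
PI 315067	PI 315067	874	Former Soviet Union	NA	NA	uncertain	NA	unknown	NA	table2	TRUE
PI 315354	PI 315354	876	Russia	Stavropol	NA	wild	NA	unknown	NA	table2	TRUE
PI 325190	PI 325190	831	Russia	Stavropol	NA	wild	NA	unknown	NA	table2	TRUE
PI 345586	PI 345586	882	Russia	Rostov Region	NA	cultivated	Rostovskii 31	unknown	NA	table2	TRUE
PI 401014	PI 401014	887	Turkey	Zongulkad	60	wild	NA	unknown	NA	table2	TRUE
PI 401015	PI 401015	755	Turkey	Sinop	30	wild	NA	unknown	NA	table2	TRUE
PI 440005	PI 440005	794	Russia	Stavropol	NA	cultivated	Stavropol-10	unknown	NA	table2	TRUE
PI 440009	PI 440009	798	Russia	E Stavropol	600	wild	NA	unknown	NA	table2	TRUE
PI 440018	PI 440018	902	Russia	SE Svetlograd	300	wild	NA	unknown	NA	table2	TRUE
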