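accession_id	pi_number	rodale_accession	origin_country	collection_site	elevation_m	status	cultivar_name	acquisition_mode	acquisition_year	source_table	molecular
PI 173630	PI 173630	NA	Turkey	Solhan	NA	wild	NA	unknown	NA	table3	TRUE
PI 486197	PI 486197	NA	Turkmenistan	NA	NA	wild	NA	unknown	NA	table3	TRUE
PI 502351	PI 502351	NA	Russia	Elista	120	cultivated	NA	unknown	NA	table3	TRUE
PI 502356	PI 502356	NA	Russia	Stvropol	500	cultivated	NA	unknown	NA	table3	TRUE
PI 547315	PI 547315	NA	Russia	Leningrad Oblast	NA	wild	NA	unknown	NA	table3	TRUE
PI 547318	PI 547318	NA	Russia	NA	NA	cultivated	NA	unknown	NA	table3	TRUE
PI 547319	PI 547319	NA	Russia	Leningrad Oblast	NA	wild	NA	unknown	NA	table3	TRUE
PI 547334	PI 547334	NA	Poland	NA	NA	wild	NA	unknown	NA	table3	TRUE
PI 574518	PI 574518	NA	USA	NA	NA	breeding_material	NA	unknown	NA	table3	TRUE
PI 578695	PI 578695	NA	USA	NA	NA	breeding_material	NA	unknown	NA	table3	TRUE
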