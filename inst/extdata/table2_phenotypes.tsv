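accession_id	trait	year	value
PI 210992	hundred_seed_weight_g	1988	0.62
PI 210992	hundred_seed_weight_g	1989	0.46
PI 210992	seed_set_rating_pct	1988	38
PI 210992	seed_set_rating_pct	1989	37
PI 210992	yield_per_10_heads_g	1988	NA
PI 210992	yield_per_10_heads_g	1989	1.15
PI 273733	hundred_seed_weight_g	1988	0.37
PI 273733	hundred_seed_weight_g	1989	0.43
PI 273733	seed_set_rating_pct	1988	42
PI 273733	seed_set_rating_pct	1989	49
PI 273733	yield_per_10_heads_g	1988	NA
PI 273733	yield_per_10_heads_g	1989	2.01
PI 297876	hundred_seed_weight_g	1988	0.5
PI 297876	hundred_seed_weight_g	1989	0.42
PI 297876	seed_set_rating_pct	1988	40
PI 297876	seed_set_rating_pct	1989	22
PI 297876	yield_per_10_heads_g	1988	NA
PI 297876	yield_per_10_heads_g	1989	0.75
PI 314192	hundred_seed_weight_g	1988	0.55
PI 314192	hundred_seed_weight_g	1989	0.43
PI 314192	seed_set_rating_pct	1988	39
PI 314192	seed_set_rating_pct	1989	35
PI 314192	yield_per_10_heads_g	1988	NA
PI 314192	yield_per_10_heads_g	1989	1.36
PI 315065	hundred_seed_weight_g	1988	0.47
PI 315065	hundred_seed_weight_g	1989	0.41
PI 315065	seed_set_rating_pct	1988	40
PI 315065	seed_set_rating_pct	1989	38
PI 315065	yield_per_10_heads_g	1988	NA
PI 315065	yield_per_10_heads_g	1989	2.14
PI 315067	hundred_seed_weight_g	1988	0.42
PI 315067	hundred_seed_weight_g	1989	0.34
PI 315067	seed_set_rating_pct	1988	41
PI 315067	seed_set_rating_pct	1989	42
PI 315067	yield_per_10_heads_g	1988	NA
PI 315067	yield_per_10_heads_g	1989	3.01
PI 315354	hundred_seed_weight_g	1988	0.47
PI 315354	hundred_seed_weight_g	1989	0.48
PI 315354	seed_set_rating_pct	1988	46
PI 315354	seed_set_rating_pct	1989	42
PI 315354	yield_per_10_heads_g	1988	NA
PI 315354	yield_per_10_heads_g	1989	2.06
PI 325190	hundred_seed_weight_g	1988	0.47
PI 325190	hundred_seed_weight_g	1989	0.29
PI 325190	seed_set_rating_pct	1988	38
PI 325190	seed_set_rating_pct	1989	19
PI 325190	yield_per_10_heads_g	1988	NA
PI 325190	yield_per_10_heads_g	1989	0.71
PI 345586	hundred_seed_weight_g	1988	0.43
PI 345586	hundred_seed_weight_g	1989	0.42
PI 345586	seed_set_rating_pct	1988	47
PI 345586	seed_set_rating_pct	1989	53
PI 345586	yield_per_10_heads_g	1988	NA
PI 345586	yield_per_10_heads_g	1989	2.52
PI 401014	hundred_seed_weight_g	1988	0.5
PI 401014	hundred_seed_weight_g	1989	0.36
PI 401014	seed_set_rating_pct	1988	42
PI 401014	seed_set_rating_pct	1989	40
PI 401014	yield_per_10_heads_g	1988	NA
PI 401014	yield_per_10_heads_g	1989	1.35
PI 401015	hundred_seed_weight_g	1988	0.39
PI 401015	hundred_seed_weight_g	1989	0.24
PI 401015	seed_set_rating_pct	1988	41
PI 401015	seed_set_rating_pct	1989	10
PI 401015	yield_per_10_heads_g	1988	NA
PI 401015	yield_per_10_heads_g	1989	0.2
PI 440005	hundred_seed_weight_g	1988	0.4
PI 440005	hundred_seed_weight_g	1989	0.42
PI 440005	seed_set_rating_pct	1988	38
PI 440005	seed_set_rating_pct	1989	43
PI 440005	yield_per_10_heads_g	1988	NA
PI 440005	yield_per_10_heads_g	1989	2.56
PI 440009	hundred_seed_weight_g	1988	0.42
PI 440009	hundred_seed_weight_g	1989	0.46
PI 440009	seed_set_rating_pct	1988	39
PI 440009	seed_set_rating_pct	1989	37
PI 440009	yield_per_10_heads_g	1988	NA
PI 440009	yield_per_10_heads_g	1989	1.44
PI 440018	hundred_seed_weight_g	1988	0.44
PI 440018	hundred_seed_weight_g	1989	0.44
PI 440018	seed_set_rating_pct	1988	46
PI 440018	seed_set_rating_pct	1989	41
PI 440018	yield_per_10_heads_g	1988	NA
PI 440018	yield_per_10_heads_g	1989	2.28
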