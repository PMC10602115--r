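accession_id	trait	year	value
PI 273732	hundred_seed_weight_g	1988	0.41
PI 273732	hundred_seed_weight_g	1989	0.46
PI 273732	seed_set_rating_pct	1988	43
PI 273732	seed_set_rating_pct	1989	46
PI 273732	yield_per_10_heads_g	1988	NA
PI 273732	yield_per_10_heads_g	1989	2.81
PI 286118	hundred_seed_weight_g	1988	0.49
PI 286118	hundred_seed_weight_g	1989	0.52
PI 286118	seed_set_rating_pct	1988	45
PI 286118	seed_set_rating_pct	1989	49
PI 286118	yield_per_10_heads_g	1988	NA
PI 286118	yield_per_10_heads_g	1989	3.15
PI 314054	hundred_seed_weight_g	1988	0.42
PI 314054	hundred_seed_weight_g	1989	0.52
PI 314054	seed_set_rating_pct	1988	42
PI 314054	seed_set_rating_pct	1989	50
PI 314054	yield_per_10_heads_g	1988	NA
PI 314054	yield_per_10_heads_g	1989	3.64
PI 315353	hundred_seed_weight_g	1988	0.42
PI 315353	hundred_seed_weight_g	1989	0.42
PI 315353	seed_set_rating_pct	1988	51
PI 315353	seed_set_rating_pct	1989	38
PI 315353	yield_per_10_heads_g	1988	NA
PI 315353	yield_per_10_heads_g	1989	2.92
PI 315355	hundred_seed_weight_g	1988	0.5
PI 315355	hundred_seed_weight_g	1989	0.48
PI 315355	seed_set_rating_pct	1988	39
PI 315355	seed_set_rating_pct	1989	51
PI 315355	yield_per_10_heads_g	1988	NA
PI 315355	yield_per_10_heads_g	1989	3.36
PI 316122	hundred_seed_weight_g	1988	0.51
PI 316122	hundred_seed_weight_g	1989	0.55
PI 316122	seed_set_rating_pct	1988	49
PI 316122	seed_set_rating_pct	1989	46
PI 316122	yield_per_10_heads_g	1988	2.89
PI 316122	yield_per_10_heads_g	1989	2.99
PI 326209	hundred_seed_weight_g	1988	0.55
PI 326209	hundred_seed_weight_g	1989	0.44
PI 326209	seed_set_rating_pct	1988	51
PI 326209	seed_set_rating_pct	1989	43
PI 326209	yield_per_10_heads_g	1988	3.95
PI 326209	yield_per_10_heads_g	1989	2.02
PI 401201	hundred_seed_weight_g	1988	0.46
PI 401201	hundred_seed_weight_g	1989	0.55
PI 401201	seed_set_rating_pct	1988	45
PI 401201	seed_set_rating_pct	1989	52
PI 401201	yield_per_10_heads_g	1988	NA
PI 401201	yield_per_10_heads_g	1989	2.85
PI 440004	hundred_seed_weight_g	1988	0.51
PI 440004	hundred_seed_weight_g	1989	0.49
PI 440004	seed_set_rating_pct	1988	48
PI 440004	seed_set_rating_pct	1989	47
PI 440004	yield_per_10_heads_g	1988	3.03
PI 440004	yield_per_10_heads_g	1989	2.79
PI 440008	hundred_seed_weight_g	1988	0.42
PI 440008	hundred_seed_weight_g	1989	0.5
PI 440008	seed_set_rating_pct	1988	44
PI 440008	seed_set_rating_pct	1989	47
PI 440008	yield_per_10_heads_g	1988	NA
PI 440008	yield_per_10_heads_g	1989	2.75
PI 440011	hundred_seed_weight_g	1988	0.57
PI 440011	hundred_seed_weight_g	1989	0.45
PI 440011	seed_set_rating_pct	1988	44
PI 440011	seed_set_rating_pct	1989	47
PI 440011	yield_per_10_heads_g	1988	NA
PI 440011	yield_per_10_heads_g	1989	2.8
PI 440014	hundred_seed_weight_g	1988	0.52
PI 440014	hundred_seed_weight_g	1989	0.45
PI 440014	seed_set_rating_pct	1988	46
PI 440014	seed_set_rating_pct	1989	45
PI 440014	yield_per_10_heads_g	1988	2.14
PI 440014	yield_per_10_heads_g	1989	1.89
PI 440015	hundred_seed_weight_g	1988	0.55
PI 440015	hundred_seed_weight_g	1989	0.49
PI 440015	seed_set_rating_pct	1988	50
PI 440015	seed_set_rating_pct	1989	47
PI 440015	yield_per_10_heads_g	1988	3.46
PI 440015	yield_per_10_heads_g	1989	2.6
PI 440017	hundred_seed_weight_g	1988	0.52
PI 440017	hundred_seed_weight_g	1989	0.52
PI 440017	seed_set_rating_pct	1988	49
PI 440017	seed_set_rating_pct	1989	41
PI 440017	yield_per_10_heads_g	1988	2.49
PI 440017	yield_per_10_heads_g	1989	2.1
PI 440028	hundred_seed_weight_g	1988	0.5
PI 440028	hundred_seed_weight_g	1989	0.43
PI 440028	seed_set_rating_pct	1988	43
PI 440028	seed_set_rating_pct	1989	35
PI 440028	yield_per_10_heads_g	1988	NA
PI 440028	yield_per_10_heads_g	1989	1.25
PI 440029	hundred_seed_weight_g	1988	0.53
PI 440029	hundred_seed_weight_g	1989	0.4
PI 440029	seed_set_rating_pct	1988	43
PI 440029	seed_set_rating_pct	1989	31
PI 440029	yield_per_10_heads_g	1988	NA
PI 440029	yield_per_10_heads_g	1989	1.25
PI 440031	hundred_seed_weight_g	1988	0.59
PI 440031	hundred_seed_weight_g	1989	0.5
PI 440031	seed_set_rating_pct	1988	45
PI 440031	seed_set_rating_pct	1989	37
PI 440031	yield_per_10_heads_g	1988	2.89
PI 440031	yield_per_10_heads_g	1989	1.62
PI 440038	hundred_seed_weight_g	1988	0.57
PI 440038	hundred_seed_weight_g	1989	0.4
PI 440038	seed_set_rating_pct	1988	51
PI 440038	seed_set_rating_pct	1989	36
PI 440038	yield_per_10_heads_g	1988	3.67
PI 440038	yield_per_10_heads_g	1989	1.98
PI 440039	hundred_seed_weight_g	1988	0.64
PI 440039	hundred_seed_weight_g	1989	0.56
PI 440039	seed_set_rating_pct	1988	45
PI 440039	seed_set_rating_pct	1989	31
PI 440039	yield_per_10_heads_g	1988	2.51
PI 440039	yield_per_10_heads_g	1989	1.21
RI 31	hundred_seed_weight_g	1988	0.53
RI 31	hundred_seed_weight_g	1989	0.51
RI 31	seed_set_rating_pct	1988	51
RI 31	seed_set_rating_pct	1989	48
RI 31	yield_per_10_heads_g	1988	2.02
RI 31	yield_per_10_heads_g	1989	2.54
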