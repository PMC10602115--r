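set_name	accession_id
historical	PI 273732
historical	PI 286118
historical	PI 314054
historical	PI 315353
historical	PI 315355
historical	PI 316122
historical	PI 326209
historical	PI 401201
historical	PI 440004
historical	PI 440008
historical	PI 440011
historical	PI 440014
historical	PI 440015
historical	PI 440017
historical	PI 440028
historical	PI 440029
historical	PI 440031
historical	PI 440038
historical	PI 440039
historical	RI 31
remnant_rodale	PI 286118
remnant_rodale	PI 273732
remnant_rodale	PI 440004
remnant_rodale	PI 314054
remnant_rodale	PI 440015
remnant_rodale	PI 316122
remnant_rodale	PI 315353
remnant_rodale	PI 440011
tli_cycle6	PI 286118
tli_cycle6	PI 273732
tli_cycle6	PI 440004
tli_cycle6	PI 314054
tli_cycle6	PI 440015
tli_cycle6	PI 316122
tli_cycle6	PI 315355
tli_cycle6	PI 440017
tli_cycle6	PI 210992
tli_cycle6	PI 273733
tli_cycle6	PI 297876
tli_cycle6	PI 314192
tli_cycle6	PI 315065
tli_cycle6	PI 315067
tli_cycle6	PI 315354
tli_cycle6	PI 325190
tli_cycle6	PI 345586
tli_cycle6	PI 401014
tli_cycle6	PI 401015
tli_cycle6	PI 440005
tli_cycle6	PI 440009
tli_cycle6	PI 440018
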