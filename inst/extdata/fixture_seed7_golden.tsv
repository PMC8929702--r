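gene	sample	flavor	count
gene01	wt_ctl_1	total	54
gene01	wt_ctl_1	unique	6
gene01	wt_ctl_2	total	47
gene01	wt_ctl_2	unique	6
gene01	wt_str_1	total	41
gene01	wt_str_1	unique	8
gene01	wt_str_2	total	26
gene01	wt_str_2	unique	7
gene01	mut_ctl_1	total	52
gene01	mut_ctl_1	unique	8
gene01	mut_ctl_2	total	39
gene01	mut_ctl_2	unique	8
gene01	mut_str_1	total	53
gene01	mut_str_1	unique	8
gene01	mut_str_2	total	31
gene01	mut_str_2	unique	8
gene05	wt_ctl_1	total	0
gene05	wt_ctl_1	unique	0
gene05	wt_ctl_2	total	0
gene05	wt_ctl_2	unique	0
gene05	wt_str_1	total	0
gene05	wt_str_1	unique	0
gene05	wt_str_2	total	0
gene05	wt_str_2	unique	0
gene05	mut_ctl_1	total	0
gene05	mut_ctl_1	unique	0
gene05	mut_ctl_2	total	0
gene05	mut_ctl_2	unique	0
gene05	mut_str_1	total	0
gene05	mut_str_1	unique	0
gene05	mut_str_2	total	0
gene05	mut_str_2	unique	0
gene19	wt_ctl_1	total	76
gene19	wt_ctl_1	unique	11
gene19	wt_ctl_2	total	83
gene19	wt_ctl_2	unique	11
gene19	wt_str_1	total	58
gene19	wt_str_1	unique	11
gene19	wt_str_2	total	50
gene19	wt_str_2	unique	10
gene19	mut_ctl_1	total	51
gene19	mut_ctl_1	unique	10
gene19	mut_ctl_2	total	84
gene19	mut_ctl_2	unique	10
gene19	mut_str_1	total	56
gene19	mut_str_1	unique	11
gene19	mut_str_2	total	58
gene19	mut_str_2	unique	10
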