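taxon	dargyrome_type	FVC_count	habitat	ecozone
Euplotes_petzi	text	figure	figure	figure
Euplotes_sinicus	text	figure	figure	figure
Euplotes_focardii	figure	figure	figure	figure
Euplotes_magnicirratus	table	table	figure	figure
Euplotes_alatus	table	table	text	figure
Euplotes_balteatus	table	table	figure	figure
Euplotes_antarcticus	text	table	figure	figure
Euplotes_trisulcatus	table	table	figure	figure
Euplotes_parkei	figure	figure	figure	figure
Euplotes_quinquecarinatus	figure	figure	figure	figure
Euplotes_muscicola	text	figure	text	figure
Euplotes_muscorum	text	figure	text	figure
Euplotes_dammamensis	text	text	text	figure
Euplotes_neapolitanus	figure	figure	text	figure
Euplotes_gracilis	figure	figure	figure	figure
Euplotes_encysticus	figure	figure	figure	figure
Euplotes_novemcarinatus	figure	figure	figure	figure
Euplotes_rariseta	figure	figure	figure	figure
Euplotes_euryhalinus	figure	figure	text	figure
Euplotes_versatilis	figure	figure	figure	figure
Euplotes_minuta	text	figure	figure	figure
Euplotes_vannus	text	figure	figure	figure
Euplotes_crassus	text	figure	figure	figure
Euplotes_harpa	figure	figure	text	figure
Euplotes_woodruffi	figure	figure	text	figure
Euplotes_daidaleos	figure	figure	text	figure
Euplotes_uncinatus	figure	figure	text	figure
Euplotes_eurystomus	text	figure	text	figure
Euplotes_patella	text	figure	text	figure
Euplotes_amieti	figure	figure	text	figure
Euplotes_aediculatus	figure	figure	text	figure
Euplotes_octocarinatus	figure	figure	text	figure
Euplotes_qatarensis	text	text	text	figure
Euplotes_curdsi	text	text	text	figure
Euplotes_nobilii	text	figure	text	figure
Euplotes_raikovi	text	figure	figure	figure
Euplotes_elegans	text	figure	text	figure
Euplotes_sp_FW	figure	figure	text	figure
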