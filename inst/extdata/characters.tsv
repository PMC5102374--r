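taxon	dargyrome_type	FVC_count	habitat	ecozone
Euplotes_petzi	double-patella	10	marine	polar
Euplotes_sinicus	double-patella	10	marine	temperate
Euplotes_focardii	double-patella	10	marine	polar
Euplotes_magnicirratus	double-eurystomus	10	marine	temperate
Euplotes_alatus	double-eurystomus	10	freshwater	temperate
Euplotes_balteatus	double-eurystomus	10	marine	temperate
Euplotes_antarcticus	?	10	marine	polar
Euplotes_trisulcatus	double-eurystomus	10	marine	temperate
Euplotes_parkei	double-patella	10	marine	temperate
Euplotes_quinquecarinatus	double-patella	10	marine	temperate
Euplotes_muscicola	multiple	8	freshwater	temperate
Euplotes_muscorum	complex	8	freshwater	temperate
Euplotes_dammamensis	?	10	hypersaline	tropical
Euplotes_neapolitanus	double-eurystomus	10	marine	temperate
Euplotes_gracilis	double-eurystomus	8	marine	temperate
Euplotes_encysticus	double-eurystomus	10	marine	temperate
Euplotes_novemcarinatus	double-eurystomus	10	marine	tropical
Euplotes_rariseta	double-eurystomus	7	marine	tropical
Euplotes_euryhalinus	double-eurystomus	10	marine|brackish	temperate
Euplotes_versatilis	double-eurystomus	10	marine	?
Euplotes_minuta	single	9	marine	temperate
Euplotes_vannus	single	10	marine	temperate
Euplotes_crassus	single	10	marine	temperate
Euplotes_harpa	double-eurystomus	10	brackish	temperate
Euplotes_woodruffi	double-eurystomus	9	freshwater|brackish	temperate
Euplotes_daidaleos	double-eurystomus	10	freshwater	temperate
Euplotes_uncinatus	double-eurystomus	10	freshwater	temperate
Euplotes_eurystomus	double-eurystomus	10	freshwater	temperate
Euplotes_patella	double-patella	10	freshwater	temperate
Euplotes_amieti	double-patella	10	freshwater	tropical
Euplotes_aediculatus	double-patella	9	freshwater	temperate
Euplotes_octocarinatus	double-patella	9	freshwater	temperate
Euplotes_qatarensis	double-eurystomus	10	hypersaline	tropical
Euplotes_curdsi	double-eurystomus	10	brackish|marine	temperate
Euplotes_nobilii	double-patella	10	marine	polar
Euplotes_raikovi	double-patella	9	marine	temperate
Euplotes_elegans	double-patella	10	marine	temperate
Euplotes_sp_FW	?	10	freshwater	temperate
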