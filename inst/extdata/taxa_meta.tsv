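taxon	clade	subclade	notes
Euplotes_petzi	E	sc_petzi	early-branching; Antarctic
Euplotes_sinicus	E	sc_petzi	early-branching
Euplotes_focardii	D	sc_focardii	Antarctic, cold-adapted
Euplotes_magnicirratus	D	sc_focardii	thick transverse cirri
Euplotes_alatus	D	sc_alatus	only sequence from a freshwater pond
Euplotes_balteatus	D	sc_alatus	extremely plastic size
Euplotes_antarcticus	D	sc_alatus	argyrome not discernible in original description
Euplotes_trisulcatus	D	sc_alatus	
Euplotes_parkei	D	sc_parkei	
Euplotes_quinquecarinatus	D	sc_parkei	
Euplotes_muscicola	A	sc_muscicola	soil/freshwater; multiple dargyrome
Euplotes_muscorum	A	sc_muscicola	complex dargyrome within muscicola subclade
Euplotes_dammamensis	A	sc_dammamensis	argyrome unknown; >100 um; hypersaline
Euplotes_neapolitanus	A	sc_dammamensis	described from sea samples only
Euplotes_gracilis	A	sc_gracilis	
Euplotes_encysticus	A	sc_gracilis	large intraspecific variability
Euplotes_novemcarinatus	A	sc_gracilis	
Euplotes_rariseta	A	sc_rariseta	
Euplotes_euryhalinus	A	sc_rariseta	markedly euryhaline
Euplotes_versatilis	A	sc_rariseta	supergiant-forming
Euplotes_minuta	A	sc_vannus	
Euplotes_vannus	A	sc_vannus	single dargyrome subclade
Euplotes_crassus	A	sc_vannus	
Euplotes_harpa	B	sc_harpa	brackish-euryhaline; Polynucleobacter symbiosis
Euplotes_woodruffi	B	sc_woodruffi	macronucleus T-shaped (unique in the genus); euryhaline
Euplotes_daidaleos	B	sc_daidaleos	harbors endocellular algae
Euplotes_uncinatus	B	sc_daidaleos	harbors endocellular algae
Euplotes_eurystomus	B	sc_eurystomus	freshwater radiation of clade B
Euplotes_patella	B	sc_patella	freshwater radiation of clade B
Euplotes_amieti	B	sc_patella	
Euplotes_aediculatus	B	sc_patella	Polynucleobacter host
Euplotes_octocarinatus	B	sc_patella	
Euplotes_qatarensis	C	sc_curdsi	hypersaline; 10 kineties; anterior projection
Euplotes_curdsi	C	sc_curdsi	three populations: Min 12, AgTo 32, WSea 25 permille
Euplotes_nobilii	C	sc_curdsi	polar; best BLAST hit of E. curdsi (97.4%)
Euplotes_raikovi	C	sc_curdsi	
Euplotes_elegans	C	sc_curdsi	
Euplotes_sp_FW	C	sc_curdsi	undescribed freshwater population related to E. elegans
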