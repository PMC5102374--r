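population	locality	salinity_permille
Min	Orbetello Lagoon, Italy	12
AgTo	Agrigento, Italy	32
WSea	Sredny Island, White Sea, Russia	25
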