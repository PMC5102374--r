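(sc_petzi:0.08,((sc_muscicola:0.06,sc_dammamensis:0.05,sc_gracilis:0.05,sc_rariseta:0.05,sc_vannus:0.05)79/0.95:0.014,(((sc_focardii:0.05,sc_alatus:0.05)90/0.99:0.009,sc_parkei:0.05)86/0.97:0.013,((sc_harpa:0.05,(sc_woodruffi:0.05,(sc_daidaleos:0.04,(sc_eurystomus:0.03,sc_patella:0.03)90/0.99:0.008)84/0.97:0.007)88/0.98:0.008)97/1.00:0.012,sc_curdsi:0.05)89/0.99:0.010)76/0.94:0.008)80/0.96:0.009);
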