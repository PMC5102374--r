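((Euplotes_petzi:0.052,Euplotes_sinicus:0.048)100/1.00:0.031,(((Euplotes_muscicola:0.046,Euplotes_muscorum:0.049)100/1.00:0.022,(Euplotes_dammamensis:0.051,Euplotes_neapolitanus:0.043)97/1.00:0.010,(Euplotes_gracilis:0.038,(Euplotes_encysticus:0.035,Euplotes_novemcarinatus:0.037)91/0.99:0.009)85/0.98:0.008,(Euplotes_rariseta:0.042,(Euplotes_euryhalinus:0.033,Euplotes_versatilis:0.036)89/0.99:0.007)82/0.96:0.009,(Euplotes_minuta:0.029,(Euplotes_vannus:0.021,Euplotes_crassus:0.019)100/1.00:0.006)100/1.00:0.024)79/0.95:0.014,((((Euplotes_focardii:0.041,Euplotes_magnicirratus:0.037)98/1.00:0.012,(Euplotes_alatus:0.044,(Euplotes_balteatus:0.039,(Euplotes_antarcticus:0.028,Euplotes_trisulcatus:0.031)92/0.99:0.008)88/0.98:0.007)95/1.00:0.011)90/0.99:0.009,(Euplotes_parkei:0.036,Euplotes_quinquecarinatus:0.040)100/1.00:0.018)86/0.97:0.013,((Euplotes_harpa:0.047,(Euplotes_woodruffi:0.045,((Euplotes_daidaleos:0.032,Euplotes_uncinatus:0.034)94/1.00:0.009,(Euplotes_eurystomus:0.026,(Euplotes_patella:0.027,(Euplotes_amieti:0.030,(Euplotes_aediculatus:0.022,Euplotes_octocarinatus:0.024)96/1.00:0.005)87/0.98:0.006)93/0.99:0.010)90/0.99:0.008)84/0.97:0.007)88/0.98:0.008)97/1.00:0.012,((Euplotes_qatarensis:0.049,(Euplotes_curdsi:0.023,(Euplotes_nobilii:0.025,Euplotes_raikovi:0.027)100/1.00:0.009)95/1.00:0.007)83/0.96:0.008,(Euplotes_elegans:0.038,Euplotes_sp_FW:0.041)92/0.99:0.010)98/1.00:0.015)89/0.99:0.010)76/0.94:0.008)80/0.96:0.009);
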