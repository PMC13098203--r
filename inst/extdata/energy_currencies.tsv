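currency	equation
atp	atp_c + h2o_c -> adp_c + pi_c + h_c
gtp	gtp_c + h2o_c -> gdp_c + pi_c + h_c
nadh	nadh_c -> nad_c + h_c
nadph	nadph_c -> nadp_c + h_c
fadh2	fadh2_c -> fad_c + 2 h_c
proton_gradient	h_e -> h_c
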