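exchange_id	class
EX_glu__L_e	amino_acid
EX_leu__L_e	amino_acid
EX_cys__L_e	amino_acid
EX_met__L_e	amino_acid
EX_so4_e	mineral
EX_pi_e	mineral
EX_nh4_e	mineral
EX_h2o_e	free
EX_h_e	free
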