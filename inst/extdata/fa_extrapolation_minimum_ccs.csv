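species,carbon_chain,pi_bond_position,exp_ccs,calc_ccs,reported_pct_error
gamma-tocopherol,22,,207.14,241.98,16.82
Lignoceric acid,24,,200.36,283.11,41.30
Nervonic acid,24,D15,197.48,245.13,24.13
Tricosylic acid,23,,196.88,263.54,33.86
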