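species,carbon_chain,pi_bond_position,exp_ccs,calc_ccs,reported_pct_error
gamma-tocopherol,22,,207.14,214.47,3.54
Lignoceric acid,24,,200.36,288.92,44.20
Nervonic acid,24,D15,197.48,232.92,17.95
Tricosylic acid,23,,196.88,276.03,40.20
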