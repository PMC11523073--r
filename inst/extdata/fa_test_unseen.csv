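species,carbon_chain,pi_bond_position,exp_ccs,calc_ccs,reported_pct_error
Adrenic acid,22,D7;10;13;16,189.97,185.26,2.48
DHA,22,D4;7;10;13;16;19,190.17,189.75,0.22
Carb. Thromb. A2,22,,201.10,197.87,1.61
Artemisic acid,18,D9;11,182.20,189.44,3.97
14S-HDHA,22,D4;7;10;12;16;19,189.29,180.43,4.68
13-Oxo-ODE,18,D9;11,179.53,175.42,2.29
17S-HDHA,22,D4;7;10;13;15;19,193.67,191.94,0.89
Gondoic acid,20,cis-D11,183.69,187.64,2.15
Glutarylcarnitine,5,,165.30,167.25,1.18
Lipoxin A4,20,D7;9;11;13,193.03,192.01,0.53
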