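species,carbon_chain,pi_bond_position,exp_ccs,calc_ccs,reported_pct_error
Vaccenic acid,18,trans-D11,174.95,235.72,34.74
Oleic acid,18,cis-D9,175.22,177.16,1.11
Petroselinic acid,18,cis-D6,175.50,183.34,4.47
Elaidic acid,18,trans-D6,175.90,188.99,7.44
alpha-Linolenic acid,18,D9;12;15,174.26,168.99,3.02
gamma-Linolenic acid,18,D6;9;12,174.77,181.54,3.87
Dihomo-gamma-linolenic acid,20,D8;11;14,182.36,184.54,1.20
Eicosatrienoic acid,20,D11;14;17,178.70,178.13,0.32
5(S)-HETE,20,D6;8;11;14,186.27,177.50,4.71
12(R)-HETE,20,D5;8;10;14,183.18,184.93,0.96
15(S)-HETE,20,D5;8;11;13,184.77,190.10,2.88
15-OxoETE,20,D5;8;11;13,183.13,195.25,6.62
14(15)-EpETE,20,D5;8;11;17,183.90,177.20,3.64
5-OxoETE,20,D6;8;11;14,185.13,180.58,2.46
15(S)-HEPE,20,D5;8;11;13;17,183.07,189.06,3.27
7(R)-Maresin-1,22,D4;8;10;12;16;19,192.57,199.05,3.37
8(S)-HETE,20,D5;9;11;14,184.14,188.89,2.58
7(S)-Maresin-1,22,D4;8;10;12;16;19,192.54,199.75,3.74
PGE1,20,D9;11;15,190.23,192.52,1.20
PGF2alpha,20,D9;11;15,192.34,190.13,1.15
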