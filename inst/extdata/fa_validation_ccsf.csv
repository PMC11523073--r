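species,carbon_chain,pi_bond_position,exp_ccs,calc_ccs,reported_pct_error
Vaccenic acid,18,trans-D11,174.95,175.55,0.34
Oleic acid,18,cis-D9,175.22,171.77,1.97
Petroselinic acid,18,cis-D6,175.50,171.78,2.12
Elaidic acid,18,trans-D6,175.90,172.53,1.92
gamma-Linolenic acid,18,D6;9;12,174.77,173.81,0.55
Eicosatrienoic acid,20,D11;14;17,178.70,192.41,7.67
5(S)-HETE,20,D6;8;11;14,186.27,184.77,0.81
15-OxoETE,20,D5;8;11;13,183.13,184.16,0.56
14(15)-EpETE,20,D5;8;11;17,183.90,187.64,2.03
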