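row,IF-80,B05[O-S],Sp_Min2_Bh_i,IVDE,G2e,H6e,B05[N-Cl]
X,0,0,2.069,1.841,0.151,0.977,0
Xstar,0,0,2.082,1.811,0.173,0.997,0
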