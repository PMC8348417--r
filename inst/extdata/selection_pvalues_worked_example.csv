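electrode,channel,p_neg_neu,p_neg_pos,p_neu_pos,decision
1,AF3,0.001,0.8130,0.001,reject
2,AF4,0.001,0.001,0.001,adopt
3,FT7,0.5900,0.0365,0.2916,reject
4,FT8,0.001,0.001,0.001,adopt
5,T7,0.1053,0.001,0.001,reject
6,T8,0.001,0.001,0.001,adopt
7,TP7,0.0029,0.001,0.8367,reject
8,TP8,0.0225,0.001,0.001,adopt
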