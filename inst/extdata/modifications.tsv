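name	delta_da	composition	residues	printed_delta
TMT	229.162932	C8(13C)4H20N(15N)O2	K,N-term	229.163
Carbamidomethyl	57.021464	C2H3NO	C	57.021
Oxidation	15.994915	O	M	15.995
Phospho	79.966331	HPO3	S,T,Y	79.966
Deamidation	0.984016		N,Q	0.984
GlyGly	114.042927	C4H6N2O2	K	114.0429
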