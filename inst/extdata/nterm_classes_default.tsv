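class	residues
NERD	R,K,H,F,W,Y,L,I,D,E,N,Q
other	A,S,T,C,G,V
unchanged	M,P
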