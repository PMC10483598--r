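gene	loci
TP53	R175H,R248Q,R273H,R282W,G245S,Y220C,R248W,R273C
KRAS	G12D,G12V,G12C,G13D,Q61H,A146T,G12R
EGFR	L858R,E746_A750DEL,T790M,G719A,L861Q
PIK3CA	E545K,H1047R,E542K,N345K,C420R,Q546K
APC	R1450*,R876*,E1309FS,T1556FS,R232*,Q1378*
MYC	T58I,P59L,S62F
PTEN	R130G,R233*,R173H,T319FS,R130Q
ERBB2	S310F,L755S,V777L,Y772_A775DUP
CDKN2A	R58*,H83Y,D108N,W110*
ARID1A	Q456*,R1276*,G1847FS,Q1519FS
SMAD4	R361H,R361C,D351H,G386D
BRAF	V600E,V600K,G469A,D594G
IDH1	R132H,R132C,R132G
FBXW7	R465C,R479Q,R505C
BRCA2	S1982FS,R2318*,E1493FS
GNAS	R201C,R201H,Q227L
NF1	R440*,Q1174*,R1947*,L844F
CTNNB1	S45F,S37F,T41A,D32Y
ATM	R337C,R3008H,Q1970*
CCNE1	R95Q,D104N
ESR1	D538G,Y537S,Y537N,E380Q
FGFR1	N546K,K656E
MET	Y1253D,D1228N,X1010_SPLICE
CDK4	R24C,K22Q
KIT	D816V,W557_K558DEL,V559D,L576P
FGFR2	S252W,N549K,C382R
NRAS	Q61K,Q61R,G12D,G13R
AKT1	E17K,L52R
FGFR3	S249C,Y373C,R248C
MAP2K1	K57N,Q56P,P124S
VHL	R167W,S65L,L89P
HRAS	G12S,Q61L,G13R
GNA11	Q209L,R183C
GNAQ	Q209P,Q209L,R183Q
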