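name	smiles	formula	skeleton_block	stereo_smiles
D-glucose	OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O	C6H12O6	WQZGKKKJIJFFOK	OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O;OC[C@H]1O[C@@H](O)[C@H](O)[C@@H](O)[C@@H]1O;OC[C@H]1O[C@H](O)[C@H](O)[C@@H](O)[C@@H]1O
D-fructose	OCC1(O)OC[C@@H](O)[C@@H](O)[C@@H]1O	C6H12O6	LKDRXBCSQODPBY	
glycine	NCC(=O)O	C2H5NO2	DHMQDGOQFOQNFH	
L-alanine	C[C@@H](N)C(=O)O	C3H7NO2	QNAYBMKLOCPYGJ	C[C@@H](N)C(=O)O;C[C@H](N)C(=O)O
L-serine	OC[C@@H](N)C(=O)O	C3H7NO3	MTCFGRXMJLQNBG	
L-threonine	C[C@@H](O)[C@@H](N)C(=O)O	C4H9NO3	AYFVYJQAPQTCCC	C[C@@H](O)[C@@H](N)C(=O)O;C[C@H](O)[C@H](N)C(=O)O;C[C@@H](O)[C@H](N)C(=O)O
L-phenylalanine	N[C@@H](Cc1ccccc1)C(=O)O	C9H11NO2	COLNVLDHVKWLRT	
L-tyrosine	N[C@@H](Cc1ccc(O)cc1)C(=O)O	C9H11NO3	OUYCCCASQSFEME	
L-tryptophan	N[C@@H](Cc1c[nH]c2ccccc12)C(=O)O	C11H12N2O2	QIVBCDIJIAJPQS	
L-glutamine	NC(=O)CC[C@H](N)C(=O)O	C5H10N2O3	ZDXPYRJPNDTMRX	
L-glutamic acid	N[C@@H](CCC(=O)O)C(=O)O	C5H9NO4	WHUUTDBJXJRKMK	
L-aspartic acid	N[C@@H](CC(=O)O)C(=O)O	C4H7NO4	CKLJMWTZIZZHCS	
L-leucine	CC(C)C[C@H](N)C(=O)O	C6H13NO2	ROHFNLRQFUQHCH	
L-valine	CC(C)[C@@H](N)C(=O)O	C5H11NO2	KZSNJWFQEVHDMF	
L-proline	OC(=O)[C@@H]1CCCN1	C5H9NO2	ONIBWKKTOPOVIA	
caffeine	Cn1cnc2c1c(=O)n(C)c(=O)n2C	C8H10N4O2	RYYVLZVUVIJVGH	
theobromine	Cn1cnc2c1c(=O)[nH]c(=O)n2C	C7H8N4O2	YAPQBXQYLJRXSA	
adenine	Nc1ncnc2[nH]cnc12	C5H5N5	GFFGJBXGBJISGV	
guanine	Nc1nc2[nH]cnc2c(=O)[nH]1	C5H5N5O	UYTPUPDQBNUYGX	
cytosine	Nc1cc[nH]c(=O)n1	C4H5N3O	OPTASPLRGRRNAP	
uracil	O=c1cc[nH]c(=O)[nH]1	C4H4N2O2	ISAKRJDGNUQOIC	
thymine	Cc1c[nH]c(=O)[nH]c1=O	C5H6N2O2	RWQNBRDOKXIBIV	
hypoxanthine	O=c1[nH]cnc2[nH]cnc12	C5H4N4O	FDGQSTZJBFJUBT	
citric acid	OC(=O)CC(O)(CC(=O)O)C(=O)O	C6H8O7	KRKNYBCHXYNGOX	
succinic acid	OC(=O)CCC(=O)O	C4H6O4	KDYFGRWQOYBRFD	
fumaric acid	OC(=O)/C=C/C(=O)O	C4H4O4	VZCYOOQTPOCHFL	
L-malic acid	OC(=O)C[C@H](O)C(=O)O	C4H6O5	BJEPYKJPYRNKOW	OC(=O)C[C@H](O)C(=O)O;OC(=O)C[C@@H](O)C(=O)O
lactic acid	C[C@H](O)C(=O)O	C3H6O3	JVTAAEKCZFNVCJ	C[C@H](O)C(=O)O;C[C@@H](O)C(=O)O
pyruvic acid	CC(=O)C(=O)O	C3H4O3	LCTONWCANYUPML	
oxaloacetic acid	OC(=O)CC(=O)C(=O)O	C4H4O5	KHPXUQMNIQBQEV	
alpha-ketoglutaric acid	OC(=O)CCC(=O)C(=O)O	C5H6O5	KPGXRSRHYNQIFN	
benzene	c1ccccc1	C6H6	UHOVQNZJYSORNB	
toluene	Cc1ccccc1	C7H8	YXFVVABEGXRONW	
phenol	Oc1ccccc1	C6H6O	ISWSIDIOOBJBQZ	
aniline	Nc1ccccc1	C6H7N	PAYRUJLWNCNPSJ	
benzoic acid	OC(=O)c1ccccc1	C7H6O2	WPYMKLBDIGXBTP	
salicylic acid	OC(=O)c1ccccc1O	C7H6O3	YGSDEFSMJLZEOE	
acetylsalicylic acid	CC(=O)Oc1ccccc1C(=O)O	C9H8O4	BSYNRYMUTXBXSQ	
paracetamol	CC(=O)Nc1ccc(O)cc1	C8H9NO2	RZVAJINKPMORJF	
ibuprofen	CC(C)Cc1ccc(cc1)C(C)C(=O)O	C13H18O2	HEFNNWSXXWATRW	
naphthalene	c1ccc2ccccc2c1	C10H8	UFWIBTONFRDIAS	
anthracene	c1ccc2cc3ccccc3cc2c1	C14H10	MWPLVEDNUUSJAV	
phenanthrene	c1ccc2ccc3ccccc3c2c1	C14H10	YNPNZTXNASCQKK	
anthraquinone	O=C1c2ccccc2C(=O)c2ccccc21	C14H8O2	RZVHIXYEVGDQDX	
1-aminoanthraquinone	Nc1cccc2C(=O)c3ccccc3C(=O)c12	C14H9NO2	KHUFHLFHOQVFGB	
2-aminoanthraquinone	Nc1ccc2C(=O)c3ccccc3C(=O)c2c1	C14H9NO2	XOGPDSATLSAZEK	
pyridine	c1ccncc1	C5H5N	JUJWROOIHBZHMG	
quinoline	c1ccc2ncccc2c1	C9H7N	SMWDFEZZVXVKRB	
indole	c1ccc2[nH]ccc2c1	C8H7N	SIKJAQJRHWYJAI	
nicotinamide	NC(=O)c1cccnc1	C6H6N2O	DFPAKSUCGFBDDF	
nicotine	CN1CCC[C@H]1c1cccnc1	C10H14N2	SNICXCGAKADSCV	
butan-2-ol	CC[C@H](C)O	C4H10O	BTANRVKWQNVYAZ	CC[C@H](C)O;CC[C@@H](C)O
glycerol	OCC(O)CO	C3H8O3	PEDCQBHIVMGVHV	
urea	NC(=O)N	CH4N2O	XSQUKJJJFZCRTK	
ethanol	CCO	C2H6O	LFQSCWFLJHTTHZ	
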