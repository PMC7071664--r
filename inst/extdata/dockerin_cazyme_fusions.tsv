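host_species	origin	sex	tissue	taxon	families
A_aquaticus	field	female	non_digestive	Bacteria	GH35
A_aquaticus	field	female	non_digestive	Bacteroidetes	GH130
A_aquaticus	field	female	non_digestive	Cytophagales	GH35
A_aquaticus	field	male	non_digestive	Bacteria	GH130
A_aquaticus	field	male	non_digestive	Cytophagales	GH35
A_aquaticus	laboratory	female	hindgut	Bacteria	GH3
A_aquaticus	laboratory	male	hindgut	Armatimonadetes	CE10
A_aquaticus	laboratory	male	hindgut	Bacteria	GH18
A_aquaticus	laboratory	male	hindgut	Bacteria	GH136
A_aquaticus	laboratory	male	hindgut	Bacteria	GH2
A_aquaticus	laboratory	male	hindgut	Bacteria	GH50
A_aquaticus	laboratory	male	hindgut	Bacteria	PL9_2
A_aquaticus	laboratory	male	hindgut	Bacteria	CE1
A_aquaticus	laboratory	male	hindgut	Bacteria	GH5_13
A_aquaticus	laboratory	male	hindgut	Bacteria	GH93
A_aquaticus	laboratory	male	hindgut	Bacteria	GH99
A_aquaticus	laboratory	male	hindgut	Bacteria	GH135
A_aquaticus	laboratory	male	hindgut	Phycisphaerae	GH99
A_aquaticus	laboratory	male	hindgut	Planctomycetes	GH44
A_aquaticus	laboratory	male	hindgut	Planctomycetes	GH26 + CBM35
A_aquaticus	laboratory	male	hindgut	Planctomycetes	GH18
A_aquaticus	laboratory	male	hindgut	Planctomycetes	GH43_5
A_aquaticus	laboratory	male	hindgut	Planctomycetes	CE1
A_aquaticus	field	female	non_digestive	Polynucleobacter	GT102
P_dilatatus_dilatatus	laboratory	male	non_digestive	Algoriphagus	GH33
P_dilatatus_petiti	laboratory	female	hindgut	Algoriphagus	CBM38
P_dilatatus_petiti	laboratory	female	non_digestive	Bacteroidetes	CBM32
P_pruinosus	field	female	hindgut	Bacteroidetes	CE3
P_pruinosus	field	female	hindgut	Rhizobiales	GH108
P_pruinosus	laboratory	female	caeca	Rhizobiales	CE10
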