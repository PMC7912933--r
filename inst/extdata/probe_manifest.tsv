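marker	species	accession
ACT1	C. albicans	AJ389057
ACT1	C. auris	AJ389073
ACT1	C. glabrata	AJ389073
ACT1	C. metapsilosis	AJ508485
ACT1	C. parapsilosis	AJ508485
ACT1	C. orthopsilosis	AJ508485
ACT1	C. tropicalis	AJ508499
ACT1	S. cerevisiae	AJ389075
ITS	C. albicans	AB032172
ITS	C. auris	AB375772
ITS	C. glabrata	AY046165
ITS	C. metapsilosis	FJ872019
ITS	C. parapsilosis	KP054272
ITS	C. orthopsilosis	FJ872018
ITS	C. tropicalis	AF287910
ITS	S. cerevisiae	AY046146
LSU	C. albicans	U45776
LSU	C. auris	AB375773
LSU	C. glabrata	U44808
LSU	C. metapsilosis	AY497667
LSU	C. parapsilosis	U45754
LSU	C. orthopsilosis	FJ746056
LSU	C. tropicalis	U45749
LSU	S. cerevisiae	AY048154
RPB1	C. albicans	JQ713048
RPB1	C. auris	MK294611.1
RPB1	C. glabrata	AY497705
RPB1	C. metapsilosis	LN680790.1:15517-16901
RPB1	C. parapsilosis	XM_714321.2
RPB1	C. orthopsilosis	LN680790.1:15517-16901
RPB1	C. tropicalis	CP017630.1:2260358-2265544
RPB1	S. cerevisiae	JQ713023
RPB2	C. albicans	XM_713079.2
RPB2	C. auris	XM_029033121.1
RPB2	C. glabrata	AF527898
RPB2	C. metapsilosis	LN680773.1:56482-58821
RPB2	C. parapsilosis	JQ698980
RPB2	C. orthopsilosis	LN680773.1:56482-58821
RPB2	C. tropicalis	CP017623.1:319665-323369
RPB2	S. cerevisiae	JQ698955
TEF1a	C. albicans	AF402066
TEF1a	C. auris	AF402029
TEF1a	C. glabrata	AF402029
TEF1a	C. metapsilosis	LN680790.1:1502560-1503683
TEF1a	C. parapsilosis	AF402066
TEF1a	C. orthopsilosis	LN680790.1:1502560-1503683
TEF1a	C. tropicalis	AF402066
TEF1a	S. cerevisiae	AF402004
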