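accession	genus	species
GCA_001298625.1	Saccharomyces	S. bayanus
GCA_001515405.2	Saccharomyces	S. bayanus
GCA_003327605.1	Saccharomyces	S. bayanus
GCA_013180675.1	Saccharomyces	S. bayanus
GCA_013180065.1	Saccharomyces	S. bayanus
GCA_013180125.1	Saccharomyces	S. bayanus
GCA_013180165.1	Saccharomyces	S. bayanus
GCA_013180695.1	Saccharomyces	S. bayanus
GCA_003086655.1	Saccharomyces	S. cerevisiae
GCA_004328465.1	Saccharomyces	S. cerevisiae
GCA_000662435.2	Saccharomyces	S. cerevisiae
GCA_000976845.3	Saccharomyces	S. cerevisiae
GCA_000977385.2	Saccharomyces	S. cerevisiae
GCA_000977715.4	Saccharomyces	S. cerevisiae
GCA_003275125.1	Saccharomyces	S. cerevisiae
GCA_002571405.2	Saccharomyces	S. cerevisiae
GCA_003274825.1	Saccharomyces	S. cerevisiae
GCA_009738405.1	Saccharomyces	S. cerevisiae
GCA_000167075.2	Saccharomyces	S. kudriavzevii
GCA_000256825.1	Saccharomyces	S. kudriavzevii
GCA_000257025.1	Saccharomyces	S. kudriavzevii
GCA_000256985.1	Saccharomyces	S. kudriavzevii
GCA_900682665.1	Saccharomyces	S. kudriavzevii
GCA_000257045.1	Saccharomyces	S. kudriavzevii
GCA_000256845.1	Saccharomyces	S. kudriavzevii
GCA_000257085.1	Saccharomyces	S. kudriavzevii
GCA_000257105.1	Saccharomyces	S. kudriavzevii
GCA_003327635.1	Saccharomyces	S. kudriavzevii
GCA_001515445.2	Saccharomyces	S. pastorianus
GCA_011022315.1	Saccharomyces	S. pastorianus
GCA_013180355.1	Saccharomyces	S. pastorianus
GCA_013180735.1	Saccharomyces	S. pastorianus
GCA_013179865.1	Saccharomyces	S. pastorianus
GCA_000805465.1	Saccharomyces	S. pastorianus
GCA_001515425.2	Saccharomyces	S. pastorianus
GCA_001483335.1	Saccharomyces	S. pastorianus
GCA_001640265.1	Saccharomyces	S. pastorianus
GCA_003004515.1	Saccharomyces	S. pastorianus
GCA_000167035.1	Saccharomyces	S. uvarum
GCA_013265775.1	Saccharomyces	S. uvarum
GCA_013179955.1	Saccharomyces	S. uvarum
GCA_013180055.1	Saccharomyces	S. uvarum
GCA_013180345.1	Saccharomyces	S. uvarum
GCA_013179815.1	Saccharomyces	S. uvarum
GCA_013265705.1	Saccharomyces	S. uvarum
GCA_013180195.1	Saccharomyces	S. uvarum
GCA_013180235.1	Saccharomyces	S. uvarum
GCA_013179965.1	Saccharomyces	S. uvarum
GCA_002079055.1	Saccharomyces	S. paradoxus
GCA_004353035.1	Saccharomyces	S. paradoxus
GCA_004353095.1	Saccharomyces	S. paradoxus
GCA_004353105.1	Saccharomyces	S. paradoxus
GCA_000166955.1	Saccharomyces	S. paradoxus
GCA_004352945.1	Saccharomyces	S. paradoxus
GCA_004352955.1	Saccharomyces	S. paradoxus
GCA_004352965.1	Saccharomyces	S. paradoxus
GCA_009805645.1	Saccharomyces	S. paradoxus
GCA_002079145.1	Saccharomyces	S. paradoxus
GCA_000182965.3	Candida	C. albicans
GCA_002837675.1	Candida	C. albicans
GCA_003454735.1	Candida	C. albicans
GCA_005890765.1	Candida	C. albicans
GCA_003013715.2	Candida	C. auris
GCA_008275145.1	Candida	C. auris
GCA_014217455.1	Candida	C. auris
GCA_014673535.1	Candida	C. auris
GCA_000002545.2	Candida	C. glabrata
GCA_002219185.1	Candida	C. glabrata
GCA_002219195.1	Candida	C. glabrata
GCA_010111755.1	Candida	C. glabrata
GCA_008904905.1	Candida	C. metapsilosis
GCA_900069165.1	Candida	C. metapsilosis
GCA_000304155.1	Candida	C. orthopsilosis
GCA_000315875.1	Candida	C. orthopsilosis
GCA_004334915.1	Candida	C. orthopsilosis
GCA_900002835.2	Candida	C. orthopsilosis
GCA_000982555.2	Candida	C. parapsilosis
GCA_011316035.2	Candida	C. parapsilosis
GCA_014049445.1	Candida	C. parapsilosis
GCA_014049495.1	Candida	C. parapsilosis
GCA_000633855.1	Candida	C. tropicalis
GCA_002864075.1	Candida	C. tropicalis
GCA_006942135.1	Candida	C. tropicalis
GCA_013177555.1	Candida	C. tropicalis
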