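source	target	provenance
HOXA5	SMAD1	curated PPI (editable fixture)
HOXA5	SOX2	curated PPI (editable fixture)
SOX2	AR	curated PPI (editable fixture)
SMAD1	AR	curated PPI (editable fixture)
SMAD1	SMAD4	curated PPI (editable fixture)
SMAD2	SMAD4	curated PPI (editable fixture)
SMAD3	SMAD4	curated PPI (editable fixture)
SMAD2	TGFBR1	curated PPI (editable fixture)
SMAD3	TGFBR1	curated PPI (editable fixture)
TGFBR1	TGFBR2	curated PPI (editable fixture)
TGFB1	TGFBR2	curated PPI (editable fixture)
AR	SMAD3	curated PPI (editable fixture)
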