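Small synthetic fixtures for examples and the vignette. The motif database
is a stylised miniature of PhyloTree-style nomenclature (macrohaplogroups
L3/M/N/R and a few nested subclades with plausible defining mutations); it
is NOT the real PhyloTree build. The ancestry tables carry invented
fractions with the qualitative structure of uniparental-vs-autosomal
comparisons in South Asian cohorts.
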