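# Gene -> disease-group map used when tabulating the mutation spectrum.
# Hyperphenylalaninemia (HPA) pools PAH (phenylalanine hydroxylase deficiency)
# and PTS (tetrahydrobiopterin deficiency) alleles into one 24-allele
# denominator for within-group relative frequencies.
groups:
  HPA: ["PAH", "PTS"]
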