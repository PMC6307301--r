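# Default cofactor pathway definitions.
# The biotin core and BioYM salvage route follow the standard late
# biosynthesis pathway; birA is the biotin-protein ligase (not scored).
# The cobalamin list is an editorial compilation of commonly used
# corrinoid marker genes, not a curated reference set: replace it when
# screening real genomes.
biotin:
  core_genes: [bioC, bioH, bioF, bioA, bioD, bioB]
  salvage_genes: [bioY, bioM]
  ligase: birA
cobalamin:
  core_genes: [cysG, cbiK, cbiL, cbiH, cbiF, cbiG, cbiD, cbiJ, cbiE, cbiT,
               cbiC, cbiA, cbiP, cbiB, cobU, cobT, cobS, cobC, cobD, btuR]
  salvage_genes: [btuB, btuF, btuC, btuD]
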