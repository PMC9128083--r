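# CHIP driver whitelist: one block per panel gene.
#   classes:    functional classes accepted anywhere in the gene
#   changes:    explicit protein changes accepted regardless of class
#   af_ceiling: population allele frequency below which a call is somatic
# The hotspot lists are illustrative defaults; edit to match a study's
# full mutation query list.
- gene: DNMT3A
  classes: [nonsense, frameshift, splice]
  changes: [R882H, R882C, R882S]
  af_ceiling: 0.001
- gene: TET2
  classes: [nonsense, frameshift, splice]
  changes: []
  af_ceiling: 0.001
- gene: ASXL1
  classes: [nonsense, frameshift, splice]
  changes: []
  af_ceiling: 0.001
- gene: PPM1D
  classes: [nonsense, frameshift, splice]
  changes: []
  af_ceiling: 0.001
- gene: CBL
  classes: [nonsense, frameshift, splice]
  changes: [C381R, C384Y, R420Q]
  af_ceiling: 0.001
- gene: SF3B1
  classes: [nonsense, frameshift, splice]
  changes: [K700E, K666N]
  af_ceiling: 0.001
- gene: TP53
  classes: [nonsense, frameshift, splice]
  changes: [R175H, R248W, R273H]
  af_ceiling: 0.001
- gene: GNB1
  classes: [nonsense, frameshift, splice]
  changes: [K57E]
  af_ceiling: 0.001
- gene: U2AF1
  classes: [nonsense, frameshift, splice]
  changes: [S34F, S34Y, Q157R]
  af_ceiling: 0.001
# ZBTB33 and ZNF318: truncating or any nonsynonymous change
- gene: ZBTB33
  classes: [nonsense, frameshift, splice, missense]
  changes: []
  af_ceiling: 0.001
- gene: ZNF318
  classes: [nonsense, frameshift, splice, missense]
  changes: []
  af_ceiling: 0.001
- gene: SRSF2
  classes: []
  changes: [P95H, P95L, P95R]
  af_ceiling: 0.001
- gene: IDH1
  classes: []
  changes: [R132H, R132C]
  af_ceiling: 0.001
- gene: IDH2
  classes: []
  changes: [R140Q, R172K]
  af_ceiling: 0.001
- gene: JAK2
  classes: []
  changes: [V617F]
  af_ceiling: 0.001
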