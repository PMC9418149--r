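# Hierarchical diagnostic-motif haplogroup scheme for the chicken mtDNA
# control region (1232-bp frame), centred on macrohaplogroup CDV with the
# standard major haplogroups A, B, E, F alongside.
#
# Published motif sets honoured by this file:
#   V   (cumulative): A281G, T355C, C363T
#   V2  (beyond V):   C228T, A237G, C391T
#   D1b (cumulative): A281G, C296T, T306C, A342G, G686A
# A281G is shared by the V and D1b cumulative paths and is therefore placed
# on the CDV stem; the split of the remaining D1b motifs along the
# CDV -> D -> D1 -> D1b path is a scheme design choice (only the cumulative
# set is published). Nodes marked `source: synthetic-placeholder` carry
# invented motifs at positions unused by the published sets; replace this
# file with a complete supplementary motif table for real-data analyses.
nodes:
  - name: ROOT
    parent: null
    motifs: []
    source: scheme-root
  - name: A
    parent: ROOT
    motifs: [C1050T]
    source: synthetic-placeholder
  - name: B
    parent: ROOT
    motifs: [A1101G]
    source: synthetic-placeholder
  - name: E
    parent: ROOT
    motifs: [G920A]
    source: synthetic-placeholder
  - name: F
    parent: ROOT
    motifs: [T860C]
    source: synthetic-placeholder
  - name: CDV
    parent: ROOT
    motifs: [A281G]
    source: published-cumulative
  - name: C
    parent: CDV
    motifs: [T448C]
    source: synthetic-placeholder
  - name: V
    parent: CDV
    motifs: [T355C, C363T]
    source: published-cumulative
  - name: V1
    parent: V
    motifs: [A59G]
    source: synthetic-placeholder
  - name: V2
    parent: V
    motifs: [C228T, A237G, C391T]
    source: published-cumulative
  - name: D
    parent: CDV
    motifs: [C296T]
    source: published-cumulative-assigned-split
  - name: D1
    parent: D
    motifs: [T306C]
    source: published-cumulative-assigned-split
  - name: D1a
    parent: D1
    motifs: [C500T]
    source: synthetic-placeholder
  - name: D1b
    parent: D1
    motifs: [A342G, G686A]
    source: published-cumulative-assigned-split
  - name: D2
    parent: D
    motifs: [A610G]
    source: synthetic-placeholder
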