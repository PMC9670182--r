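gene_trees: example_synthetic_gene_trees.nwk
reference: example_reference_mul_tree.nwk
lengths: example_synthetic_lengths.tsv
outgroup: Amborella_trichopoda
universe:
- Nymphaea_mexicana
- Nymphaea_tetragona
- Nymphaea_gigantea_Albert
- Nymphaea_gigantea_Hybrid1
- Nymphaea_colorata
- Nymphaea_caerulea
- Nymphaea_potamophila
- Nymphaea_prolifera
- Nymphaea_rubra
- Victoria_cruziana
- Euryale_ferox
- Nuphar_lutea
- Nuphar_advena
- Cabomba_caroliniana
- Brasenia_schreberi
- Amborella_trichopoda
- Nymphaea_Midnight
- Nymphaea_Woods_blue_goddess
hypotheses:
- hybrid: Nymphaea_Midnight
  lineage_A:
  - Nymphaea_colorata
  lineage_B:
  - Nymphaea_caerulea
- hybrid: Nymphaea_Woods_blue_goddess
  lineage_A:
  - Nymphaea_colorata
  lineage_B:
  - Nymphaea_caerulea
filter:
  min_coverage: 0.5
  require_outgroup: yes
  groups:
    a:
    - Nymphaea_Midnight
    - Nymphaea_colorata
    - Nymphaea_Woods_blue_goddess
    b:
    - Nymphaea_Woods_blue_goddess
    - Nymphaea_caerulea
    - Nymphaea_Midnight
    c:
    - Nymphaea_gigantea_Albert
    - Nymphaea_gigantea_Hybrid1
    d:
    - Nymphaea_mexicana
    - Nymphaea_tetragona
    e:
    - Nymphaea_potamophila
    - Nymphaea_prolifera
    - Nymphaea_rubra
    f:
    - Victoria_cruziana
    - Euryale_ferox
    g:
    - Nuphar_lutea
    - Nuphar_advena
    h:
    - Cabomba_caroliniana
    - Brasenia_schreberi
    i:
    - Amborella_trichopoda
summary_mode: heuristic
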