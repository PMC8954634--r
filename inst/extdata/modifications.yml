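# Built-in modification definitions: biotin (NHS-biotin labeling of lysines
# and peptide N termini) and the biotin-phenol adduct deposited on tyrosine
# by APEX2-generated phenoxyl radicals, with its diagnostic marker-ion
# neutral losses.
- name: biotin
  composition: "C10 H14 O2 N2 S1"
  delta_mass: 226.0776
  targets: [K, "n"]
  losses:
    immonium_CO: "C1 O1"
- name: biotin-phenol
  composition: "C18 H23 N3 O3 S1"
  delta_mass: 361.14601
  targets: ["Y"]
  losses:
    minus_CO: "C1 O1"
    minus_CONH3: "C1 O1 N1 H3"
    minus_C17H18N2O3: "C17 H18 N2 O3"
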