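# Published constants for an average haploid S. cerevisiae cell.
# wet_mass: g; density: g/ml; protein_mass_per_cell: g; avogadro: 1/mol.
wet_mass: 6.0e-11
density: 1.1126
cytoplasm_fraction: 0.5
protein_mass_per_cell: 4.0e-12
avogadro: 6.02214076e+23
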