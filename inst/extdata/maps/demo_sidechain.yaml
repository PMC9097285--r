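# Demonstration primary-amide (Gln/Asn side-chain) map, synthetic values.
# Applied directly to primary_sidechain units when present in the map set;
# the generic +30 cm^-1 class shift is then not applied.
kind: electrostatic_map
name: demo-sidechain
gas_phase_frequency: 1680.0
classes: [primary_sidechain]
exclusion: nearest_residues
dipole:
  magnitude: 0.37
  angle: 15.0
  offset: 0.0
coefficients:
  C:
    potential: 1600.0
  O:
    potential: -2800.0
    field_x: 1200.0
  N:
    potential: 1200.0
transition_charges:
  C: -0.09
  O: 0.068
  N: 0.022
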