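# Demonstration secondary-amide electrostatic map (synthetic values).
#
# Map file schema
# ---------------
# kind: electrostatic_map
# name:                 free-text identifier
# gas_phase_frequency:  omega_0 in cm^-1
# classes:              amide classes the map applies to
#                       (secondary, tertiary_preproline, primary_sidechain)
# exclusion:            source-atom exclusion rule for the electrostatics
#                       (nearest_residues | own_residue | none)
# dipole:               transition-dipole model: magnitude (Debye), angle
#                       (degrees from the C=O axis in the O=C-N plane,
#                       positive toward N), offset (nm along C=O from C)
# coefficients:         one stanza per map atom role (C, O, N, H); keys are
#                       potential, field_x/y/z, gradient_xx/xy/xz/yy/yz/zz,
#                       values in cm^-1 per atomic unit. Components are
#                       expressed in the local amide frame: x along C=O,
#                       z normal to the O=C-N plane. Only declared
#                       components are consumed.
# transition_charges:   per-role charges (e) for the transition-charge
#                       coupling scheme; here chosen so that the implied
#                       dipole matches the dipole model above for the ideal
#                       amide geometry.
#
# The coefficient values below are synthetic demonstration values with
# realistic orders of magnitude; they are NOT a published literature map.
kind: electrostatic_map
name: demo-backbone
gas_phase_frequency: 1650.0
classes: [secondary]
exclusion: nearest_residues
dipole:
  magnitude: 0.37
  angle: 20.0
  offset: 0.0
coefficients:
  C:
    potential: 1800.0
  O:
    potential: -3000.0
    field_x: 1500.0
    field_y: -400.0
  N:
    potential: 1200.0
transition_charges:
  C: -0.096378
  O: 0.072767
  N: 0.023611
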