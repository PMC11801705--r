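torsions:
- theta1
- theta2
- theta3
groups:
- - 1
- - 2
  - 3
dependent_dofs:
- label: r_CO_h
  category: bond_length
- label: r_CO_e
  category: bond_length
- label: r_CC
  category: bond_length
- label: a_COH
  category: bond_angle
- label: a_OCO
  category: bond_angle
- label: a_CCO
  category: bond_angle
- label: t_ring1
  category: torsion
- label: t_ring2
  category: torsion
charge_atoms:
- A1
- A2
- A3
- A4
- A5
- A6
- A7
- A8
- A9
- A10

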