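# Per-element nonbonded parameters (editable).
# Columns: element epsilon_eV R_angstrom charge_e
# epsilon: Morse well depth for the homo pair, eV (UFF D_I converted from
#          kcal/mol); R: half the UFF vdW distance x_I, Angstrom, so that the
#          mixed equilibrium distance is R_i + R_j; charge: default partial
#          charge in e (rocksalt ions carry their nominal +-0.9e; neutral
#          elements default to 0 and are usually overridden per molecule).
H   0.00191  1.4430  0.0
C   0.00455  1.9255  0.0
N   0.00299  1.8300  0.0
O   0.00260  1.7500  0.0
Na  0.00130  1.4915  0.9
Cl  0.00984  1.9735 -0.9
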