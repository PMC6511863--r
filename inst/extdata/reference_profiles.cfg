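# Ground-truth insertion free-energy profiles (synthetic fixtures).
#
# Anchor energies (kBT at 310 K) encode the reported insertion energetics:
# activation barriers 3.0 (cognate rATP), 3.3 (rGTP on-path), 7.6 (rGTP
# off-path), 6.0 (dATP on-path), 4.0 (dATP off-path); end-state stabilities
# -3.0 (rATP), -4.0 (rGTP on-path), -1.0 (dATP on-path) relative to the
# pre-insertion minimum.
#
# Anchor coordinates are a fixture convention, not measured quantities: the
# pre-insertion minimum (config 1) sits at the most negative window center,
# the transition maximum (config 3) at delta_rmsd = 0, the insertion minimum
# (config 5) at the most positive center.
#
# Off-path end states are not reported; conventions used:
#   rGTP/off end state +1.3 kBT above its pre-insertion minimum, chosen so
#     that the aligned on/off pre-insertion offset equals the 5.3 kBT
#     on-path association offset behind the 0.5%/99.5% path populations;
#   dATP/off end state -0.5 kBT (semi-inserted, about as stable as its
#     pre-insertion configuration).
# anchor: coordinate_A  energy_kBT

[rATP/cognate]
domain: -1.3 1.3
anchor: -1.3 0.0
anchor: 0.0 3.0
anchor: 1.3 -3.0

[rGTP/on]
domain: -1.3 1.3
anchor: -1.3 0.0
anchor: 0.0 3.3
anchor: 1.3 -4.0

[rGTP/off]
domain: -2.2 2.2
anchor: -2.2 0.0
anchor: 0.0 7.6
anchor: 2.2 1.3

[dATP/on]
domain: -1.3 1.3
anchor: -1.3 0.0
anchor: 0.0 6.0
anchor: 1.3 -1.0

[dATP/off]
domain: -2.6 2.6
anchor: -2.6 0.0
anchor: 0.0 4.0
anchor: 2.6 -0.5
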