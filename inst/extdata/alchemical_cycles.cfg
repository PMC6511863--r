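# Ground-truth per-pair free-energy increments (kBT) for the alchemical
# transformation rATP -> rGTP / rATP -> dATP over the 21-state lambda
# schedule (20 adjacent pairs), in the protein complex and in free solution.
#
# Only the protein-minus-solution difference is constrained by the reported
# relative binding free energies (ddGb = +3 kBT for rGTP, -1 kBT for dATP);
# the split between legs is a fixture convention.  Solution legs sum to zero
# with non-uniform per-pair structure so that per-pair estimation is still
# exercised.

[rGTP]
protein: 0.25 0.25 0.25 0.25 0.25 0.25 0.25 0.25 0.25 0.25 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.05
solution: 0.2 0.2 0.2 0.2 0.2 0.2 0.2 0.2 0.2 0.2 -0.2 -0.2 -0.2 -0.2 -0.2 -0.2 -0.2 -0.2 -0.2 -0.2

[dATP]
protein: -0.15 -0.15 -0.15 -0.15 -0.15 -0.15 -0.15 -0.15 -0.15 -0.15 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.05
solution: 0.1 0.1 0.1 0.1 0.1 0.1 0.1 0.1 0.1 0.1 -0.1 -0.1 -0.1 -0.1 -0.1 -0.1 -0.1 -0.1 -0.1 -0.1
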