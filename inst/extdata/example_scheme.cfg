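# Example kinetic-scheme configuration for `polfid fidelity --config`.
#
# [rates] entries override the packaged baseline rate constants (s^-1);
# omitted rates keep their packaged values.  [selection] carries the
# checkpoint selection free energies (kBT) and the on/off path entry
# fractions; [selection_on] (optional) describes the on-path branch and
# switches meaning of [selection] to the off-path branch when
# mode: split is set under [scheme].
#
# This example is the lumped single-branch rGTP description: 4 kBT
# rejection at pre-insertion and 4 kBT insertion inhibition, no catalytic
# selection.

[scheme]
ntp_ratio: 1
mode: lumped

[selection]
delta_b_minus: 4
delta_in_plus: 4
delta_in_minus: 0
delta_c_plus: 0
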