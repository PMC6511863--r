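# Baseline (cognate) rate constants for the five-state nucleotide-addition
# cycle, s^-1.  Binding steps are pseudo-first-order at the working NTP
# availability.  These values are packaged defaults, calibrated so that the
# cognate cycle elongates at a T7-like ~200 nt/s with the insertion step
# rate-limiting, and documented here as the rate set behind every fidelity
# result; they are not measured quantities of this package.
#
#   I  <-> II   translocation          k_I_plus / k_II_minus
#   II <-> III  NTP binding            k_II_plus / k_III_minus
#   III<-> IV   insertion              k_III_plus / k_IV_minus
#   IV <-> V    catalysis              k_IV_plus / k_V_minus
#   V  <-> I'   PPi release            k_V_plus / k_I_minus

[baseline]
k_I_plus: 4000
k_II_minus: 500
k_II_plus: 3000
k_III_minus: 1000
k_III_plus: 900
k_IV_minus: 25
k_IV_plus: 500
k_V_minus: 1
k_V_plus: 2000
k_I_minus: 0.1
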