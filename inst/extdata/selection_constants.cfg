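# Packaged selection-energetics constants (kBT at 310 K).
#
# Dissociation barriers at pre-insertion are imported quantities, not
# computed by this package: the cognate nucleotide is trapped by a ~4 kBT
# dissociation barrier, the off-path non-cognate species dissociate without
# barrier, and the on-path non-cognate species are assumed trapped like the
# cognate one.
#
# on_path_offset_rGTP: free-energy offset of the on-path relative to the
# off-path rGTP pre-insertion configuration; its two-state Boltzmann weight
# gives the 0.5% / 99.5% on/off path populations.
#
# datp_offpath_baseline: the dATP off-path pre-insertion configuration is a
# translocation intermediate, thermally (~1-2 kBT) less stable than the
# post-translocation state; the midpoint 1.5 kBT is used.

[dissociation]
dE_d_c: 4.0
dE_d_on: 4.0
dE_d_off: 0.0

[offsets]
on_path_offset_rGTP: 5.3
datp_offpath_baseline: 1.5
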