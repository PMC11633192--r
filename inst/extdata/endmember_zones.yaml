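# Endmember-zone library for dual-isotope N2O source classification.
#
# The DN (DNRA) box is from the reference culture dataset shipped with this
# package. The other conventional process zones (bD, nD, NI, fD, cD) are
# usually taken from a literature compilation of isotopocule signatures;
# their numeric ranges are NOT shipped here -- copy this file, uncomment the
# templates below and fill in the ranges from your preferred compilation.
#
# Note on the cNor endmember: one compilation lists the cNor SP range as
# "7.5 permil to 3.7 permil" (order as printed) while the point endmember
# used for mixing is -5.9 +/- 2.1 permil; the apparent sign/order
# inconsistency in the former is recorded verbatim and left unresolved.
#
# Axes: sp_range is reference-frame free; d15n_range and d18o_range apply to
# substrate-referenced values (product minus substrate), per-mil.
zones:
  - name: DN
    description: DNRA (nitrate/nitrite ammonification)
    sp_range: [43.0, 49.9]
    d15n_range: [-39.9, -5.8]
    d18o_range: [14.1, 30.5]
    source: DNRA reference culture dataset shipped with isoN2O
#  - name: bD
#    description: bacterial denitrification
#    sp_range: [LOW, HIGH]
#    d15n_range: [LOW, HIGH]
#    d18o_range: [LOW, HIGH]
#    source: fill in from your compilation
#  - name: nD
#    description: nitrifier denitrification
#    source: fill in from your compilation
#  - name: NI
#    description: nitrification (hydroxylamine oxidation)
#    source: fill in from your compilation
#  - name: fD
#    description: fungal denitrification
#    source: fill in from your compilation
#  - name: cD
#    description: chemical denitrification
#    source: fill in from your compilation
endmembers:
  - name: cNor
    sp: -5.9
    sp_sd: 2.1
    source: cNor-driven denitrifying N2O production
reduction_vector:
  slope_sp_d15n: 0.96
  slope_sp_d18o: 0.45
  slope_d18o_d15n: 2.21
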