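# Default four-source nitrate profiles for the mixing model (per mil).
# AON Delta-17O is the regional snowpack endmember; terrestrial Delta-17O is
# 0 +/- 0.5 (the 0 +/- 1 terrestrial band read as +/- 2 sd). The delta-15N
# means/sds are literature-range placeholders (atmospheric/fertiliser/soil/
# waste nitrogen compilations) and should be replaced with site-specific
# values where available.
sources:
  AON:
    d15N: {mean: 0.9, sd: 1.2}
    D17O: {mean: 23.7, sd: 5.6}
  Fertilizer+Rain NH4:
    d15N: {mean: -3.0, sd: 3.0}
    D17O: {mean: 0.0, sd: 0.5}
  Soil NO3:
    d15N: {mean: 4.0, sd: 2.0}
    D17O: {mean: 0.0, sd: 0.5}
  Septic Effluent and Manure:
    d15N: {mean: 10.0, sd: 4.0}
    D17O: {mean: 0.0, sd: 0.5}
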