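standard_name,d15N,d18O,d17O
USGS-32,180,25.7,
USGS-34,-1.8,-27.9,-14.8
USGS-35,2.7,57.5,51.5
IAEA-NO-3,4.7,25.6,
GSI-NO-3,1.3,14.13,
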