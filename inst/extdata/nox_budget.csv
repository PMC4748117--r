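name,tg_per_year
Fossil fuels,24
Lightning,12
Soil emissions,12
Biomass burning,8
NH3 oxidation,3
Transport from stratosphere,0.4
Aircraft,0.4
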