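# Sidecar metadata for chemostat_rates.csv
D: 0.13
substrate_id: galacturonate
biomass_formula: CH1.8O0.5N0.2
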