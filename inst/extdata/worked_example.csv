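quantity,value
spinosad_urban_2014_micrograms,1183052498279
spinosad_contact_ld50_ug_per_bee,0.0029
spinosad_urban_2014_lethal_doses,407949137337493
urban_acres,552724
urban_load_ld50_per_acre,1500895028
pomegranate_load_ld50_per_acre,2220400221
urban_resistance_anchor,8
pomegranate_resistance,12
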