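class,group,mass_g,body_mass_kg
grazing,bull,4.4,4850
grazing,herd,2.9,3500
browsing,bull,13.7,4850
browsing,herd,8.8,3500
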