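class,species,mass_g
grazing,cattle,0.77
grazing,white_rhinoceros,0.75
grazing,bison,0.60
grazing,sheep,0.18
browsing,male_giraffe,3.3
browsing,moose,3.2
browsing,female_giraffe,2.2
browsing,kudu,0.45
browsing,goat,0.18
browsing,impala,0.14
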