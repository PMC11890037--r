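forage,group,max_g,min_g
green_grass,bull,93.3,29.4
green_grass,herd,57.9,17.6
mixed_grass,bull,86.8,51.7
mixed_grass,herd,54.0,31.9
forb,bull,59.0,18.9
forb,herd,59.0,18.9
leaf,bull,36.8,22.8
leaf,herd,29.0,15.8
bark,bull,34.2,34.2
bark,herd,20.6,20.6
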