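site,abbr,lat,lon,urbanization,n,n_pruned,ho
Mas-Nouguier,MNO,43.586,3.862,2.32,18,18,0.285
Font-Colombe,FCO,43.597,3.834,0.87,10,10,0.290
Mosson,MOS,43.637,3.812,0.70,5,5,0.290
Grammont,GRA,43.617,3.932,-0.31,29,26,0.289
Rouviere,ROU,43.664,3.668,-1.94,47,41,0.294
Zoo,ZOO,43.642,3.878,-2.19,31,25,0.292
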