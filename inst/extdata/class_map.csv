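code,name,group
141,deciduous_forest,natural
176,grassland_pasture,natural
121,developed_open,natural
142,evergreen_forest,natural
143,mixed_forest,natural
152,shrubland,natural
122,developed_low,natural
190,woody_wetlands,natural
195,herbaceous_wetlands,natural
61,fallow_idle,natural
58,clover_wildflowers,natural
1,corn,agricultural
36,alfalfa,agricultural
37,other_hay,agricultural
5,soybeans,agricultural
24,winter_wheat,agricultural
66,cherries,agricultural
69,grapes,agricultural
68,apples,apple
111,open_water,other
124,developed_high,other
123,developed_med,other
131,barren,other
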