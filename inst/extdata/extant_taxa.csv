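taxon,phase,tidal_volume_ml,mass_air_g,heat_capacity_cal_c,dt_c
Giraffa camelopardalis,inspiration,5959,6.78,1.63,16.2
Equus africanus,inspiration,1605,1.82,0.44,14
Dipsosaurus dorsalis,inspiration,0.457,5.12e-4,1.23e-4,12
Corvus brachyrhynchos,inspiration,7.25,8.14e-3,1.95e-3,26.1
Columba livia,inspiration,5.24,5.90e-3,1.41e-3,25.7
Giraffa camelopardalis,expiration,NA,6.98,1.7,9.3
Equus africanus,expiration,NA,1.86,0.45,5.3
Dipsosaurus dorsalis,expiration,NA,5.24e-4,1.3e-4,7
Corvus brachyrhynchos,expiration,NA,8.68e-3,2.1e-3,19.2
Columba livia,expiration,NA,6.28e-3,1.5e-3,19.3
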