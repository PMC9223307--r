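year,land_class,area_km2
2000,cultivated,638571
2000,woodland,938340
2000,grassland,341406
2000,water,57877
2000,construction,47197
2000,unused,21814
2005,cultivated,632019
2005,woodland,939466
2005,grassland,339984
2005,water,59481
2005,construction,52900
2005,unused,21585
2010,cultivated,627056
2010,woodland,939880
2010,grassland,339431
2010,water,59925
2010,construction,57453
2010,unused,21787
2015,cultivated,619095
2015,woodland,937085
2015,grassland,339253
2015,water,61011
2015,construction,68015
2015,unused,21846
2020,cultivated,607803
2020,woodland,940496
2020,grassland,327807
2020,water,63609
2020,construction,82884
2020,unused,21766
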