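service,land_class,vc_yuan_per_hm2
gas regulation,cultivated,480.85
gas regulation,woodland,3365.95
gas regulation,grassland,769.36
gas regulation,water,0
gas regulation,unused,0
gas regulation,construction,0
climate regulation,cultivated,855.91
climate regulation,woodland,2596.59
climate regulation,grassland,856.53
climate regulation,water,442.38
climate regulation,unused,0
climate regulation,construction,0
water conservation,cultivated,577.02
water conservation,woodland,3077.44
water conservation,grassland,769.36
water conservation,water,19618.68
water conservation,unused,28.85
water conservation,construction,0
waste disposal,cultivated,1577.19
waste disposal,woodland,1259.83
waste disposal,grassland,1259.83
waste disposal,water,17502.94
waste disposal,unused,9.62
waste disposal,construction,0
soil formation and protection,cultivated,1404.08
soil formation and protection,woodland,3750.63
soil formation and protection,grassland,1875.32
soil formation and protection,water,9.62
soil formation and protection,unused,19.23
soil formation and protection,construction,0
biodiversity conservation,cultivated,682.81
biodiversity conservation,woodland,3135.14
biodiversity conservation,grassland,1048.25
biodiversity conservation,water,2394.63
biodiversity conservation,unused,326.98
biodiversity conservation,construction,0
food production,cultivated,961.7
food production,woodland,96.17
food production,grassland,288.51
food production,water,96.17
food production,unused,9.62
food production,construction,0
raw material,cultivated,96.17
raw material,woodland,2500.42
raw material,grassland,48.08
raw material,water,9.62
raw material,unused,0
raw material,construction,0
entertainment,cultivated,9.62
entertainment,woodland,1230.98
entertainment,grassland,38.47
entertainment,water,4173.78
entertainment,unused,9.62
entertainment,construction,0
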