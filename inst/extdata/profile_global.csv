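eco_zone,climate_zone,soil_type,tillage_class,weight,npp_pot
tropical_rainforest,tropical_wet,high_activity_clay,full_till,0.10,6.5
tropical_moist_deciduous,tropical_moist,low_activity_clay,full_till,0.15,5.5
tropical_dry_forest,tropical_dry,low_activity_clay,full_till,0.10,4.0
subtropical_humid_forest,warm_temperate_moist,high_activity_clay,full_till,0.15,5.0
temperate_oceanic_forest,cool_temperate_moist,high_activity_clay,reduced_till,0.15,4.5
temperate_continental_forest,cool_temperate_dry,high_activity_clay,full_till,0.20,3.5
boreal_coniferous_forest,boreal_moist,sandy,no_till,0.05,2.0
temperate_steppe,cool_temperate_dry,sandy,full_till,0.07,2.5
desert,tropical_dry,sandy,full_till,0.03,1.5
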