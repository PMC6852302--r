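eco_zone,climate_zone,soil_type,growth_rate_tC_ha_yr,agb_max_tC_ha,root_to_shoot,litter_default_tC_ha,soc_ref_tC_ha
tropical_rainforest,tropical_wet,high_activity_clay,3.0,140,0.22,5.0,60
tropical_moist_deciduous,tropical_moist,low_activity_clay,2.0,90,0.24,5.0,45
tropical_dry_forest,tropical_dry,low_activity_clay,1.2,60,0.28,5.0,35
subtropical_humid_forest,warm_temperate_moist,high_activity_clay,1.8,80,0.28,10.0,70
temperate_oceanic_forest,cool_temperate_moist,high_activity_clay,1.5,70,0.30,13.0,85
temperate_continental_forest,cool_temperate_dry,high_activity_clay,1.0,55,0.30,13.0,50
boreal_coniferous_forest,boreal_moist,sandy,0.5,30,0.32,25.0,70
temperate_steppe,cool_temperate_dry,sandy,0.1645,3.29,0.40,1.0,40
desert,tropical_dry,sandy,0.047,0.94,0.40,0.5,20
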