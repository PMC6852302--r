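name,combustion_ef_kgCO2_GJ,upstream_best,upstream_worst
wood_chips,112.0,1.5,12.0
hard_coal,94.6,4.0,16.0
natural_gas,56.1,4.5,20.0
heating_oil,74.1,6.0,18.0
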