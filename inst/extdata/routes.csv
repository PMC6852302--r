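name,eta_be,eta_fossil,electricity_share
heat_boiler,0.85,0.90,1.0
electricity_steam,0.30,0.42,1.0
electricity_igcc,0.45,0.55,1.0
chp,0.28,0.40,0.6
biofuel_2g_pessimistic,0.35,0.90,1.0
biofuel_2g_optimistic,0.55,0.90,1.0
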