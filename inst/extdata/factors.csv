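tillage_class,f_lu,f_mg,f_i
full_till,0.71,1.00,1.00
reduced_till,0.71,1.08,1.00
no_till,0.71,1.15,1.00
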