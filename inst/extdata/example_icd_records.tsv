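individual_id	icd_code
p01	272.0
p01	272.4
p01	401.1
p01	414.00
p02	401.9
p02	427.31
p03	250.00
p03	250.02
p03	401.1
p04	162.9
p04	305.1
p04	496
p05	414.01
p05	410.90
p05	272.4
p06	799.9
p06	401.1
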