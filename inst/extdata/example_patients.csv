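id,sex,height_m,weight_kg,heart_rate_bpm,pacemaker
P001,M,1.80,80,64,false
P002,F,1.65,60,58,false
P003,F,1.71,77.5,72,false
P004,M,1.92,102,66,false
P005,F,1.58,52,81,false
P006,M,1.70,68,62,false
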