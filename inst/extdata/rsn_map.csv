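label,network
O1,VN
O2,VN
T5,VN
T6,VN
C3,SM
C4,SM
Cz,SM
P3,DA
P4,DA
Pz,DA
F7,VAL
F8,VAL
T3,VAL
T4,VAL
F3,FR
F4,FR
Fp1,FR
Fp2,FR
Fz,FR
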