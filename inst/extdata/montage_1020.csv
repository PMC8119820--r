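label,x,y,z
Fp1,-0.3088287496,0.9504771584,-0.0348994967
Fp2,0.3088287496,0.9504771584,-0.0348994967
F3,-0.5450074458,0.6730281451,0.5000000000
F4,0.5450074458,0.6730281451,0.5000000000
F7,-0.8085241631,0.5874271894,-0.0348994967
F8,0.8085241631,0.5874271894,-0.0348994967
Fz,0.0000000000,0.7193398003,0.6946583705
C3,-0.7071067812,-0.0000000000,0.7071067812
C4,0.7071067812,0.0000000000,0.7071067812
Cz,0.0000000000,0.0000000000,1.0000000000
T3,-0.9993908270,-0.0000000000,-0.0348994967
T4,0.9993908270,0.0000000000,-0.0348994967
T5,-0.8085241631,-0.5874271894,-0.0348994967
T6,0.8085241631,-0.5874271894,-0.0348994967
P3,-0.5450074458,-0.6730281451,0.5000000000
P4,0.5450074458,-0.6730281451,0.5000000000
Pz,0.0000000000,-0.7193398003,0.6946583705
O1,-0.3088287496,-0.9504771584,-0.0348994967
O2,0.3088287496,-0.9504771584,-0.0348994967
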