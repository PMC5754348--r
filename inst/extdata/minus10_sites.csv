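# -10 site library (8 parts, labels A-H). Only 'E' (GATACT) and 'F'
# (GATAAT) are authoritative sequences; the others are synthetic
# placeholders.
label,kind,sequence
A,minus10,TATACT
B,minus10,TACAAT
C,minus10,GACAAT
D,minus10,GCCACT
E,minus10,GATACT
F,minus10,GATAAT
G,minus10,TATAAT
H,minus10,GACACT
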