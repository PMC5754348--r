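# -35 site library (6 parts, labels a-f). Only 'd' (TTTACA) is an
# authoritative sequence; the others are synthetic placeholders.
label,kind,sequence
a,minus35,TTGACC
b,minus35,TCTAAA
c,minus35,TTGATA
d,minus35,TTTACA
e,minus35,TTGACA
f,minus35,TCTACA
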