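S train1
W 0 Fisetin
W 1 induces
W 2 apoptosis
W 3 in
W 4 HCT-116
W 5 cells
L 4 5 AN
L 0 1 Ss
L 1 2 Os
L 1 3 MVp
L 3 5 Js
E 1
T 0 0 @SUBSTANCE
T 2 2 @SYMPTOM
T 4 5 @BODYPART

S train2
W 0 Docetaxel
W 1 was
W 2 a
W 3 more
W 4 potent
W 5 inducer
W 6 of
W 7 apoptosis
L 0 1 Ss
L 2 5 Ds
L 3 4 EA
L 4 5 A
L 1 5 Ost
L 5 6 Mp
L 6 7 Js
E 5
T 0 0 @SUBSTANCE
T 7 7 @SYMPTOM

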