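S 19264955:1
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

S 19262372:1
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

S 18070986:1
W 0 Wogonin
W 1 induces
W 2 apoptosis
W 3 in
W 4 malignant
W 5 T
W 6 cells
L 4 5 AN
L 5 6 AN
L 0 1 Ss
L 1 2 Os
L 1 3 MVp
L 3 6 Js

S 19258429:1
W 0 Tolfenamic
W 1 acid
W 2 induces
W 3 Sp
W 4 protein
W 5 degradation
W 6 in
W 7 several
W 8 cancer
W 9 cell
W 10 lines
L 0 1 AN
L 3 4 AN
L 4 5 AN
L 7 10 Dmc
L 8 9 AN
L 9 10 AN
L 1 2 Ss
L 2 5 Os
L 2 6 MVp
L 6 10 Js

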