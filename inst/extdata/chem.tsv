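# synthetic example corpus: simplified sentences and curated reference-style chemical attributes for demonstration
name	semantic_type	smiles	formula	xlogp
Wogonin	Organic Chemical	NA	C16H12O5	2.74
Fisetin	Organic Chemical	NA	C15H10O6	2.77
Docetaxel	Pharmacologic Substance	NA	C43H53NO14	2.4
Tolfenamic acid	Organic Chemical	NA	C14H12ClNO2	5.1
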