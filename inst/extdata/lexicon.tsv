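# synthetic example corpus: simplified sentences and curated reference-style chemical attributes for demonstration
fisetin	SUBSTANCE	Organic Chemical
wogonin	SUBSTANCE	Organic Chemical
docetaxel	SUBSTANCE	Pharmacologic Substance
tolfenamic acid	SUBSTANCE	Organic Chemical
apoptosis	PROCESS	Biologic Function
sp protein degradation	PROCESS	Biologic Function
hct-116 cells	BODYPART	Cell or Tissue
malignant t cells	BODYPART	Cell or Tissue
cancer cell lines	BODYPART	Cell or Tissue
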