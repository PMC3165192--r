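induc :: M+ (of) J+ @SYMPTOM
induc :: MV+ (in) J+ @BODYPART
induc :: O- (wa) S- @SUBSTANCE
induc :: O+ @SYMPTOM
induc :: S- @SUBSTANCE
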