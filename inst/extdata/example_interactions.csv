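drug_id,target_id,ki,unit,species,source
ibuprofen_like,OPRD_HUMAN_FRAG,250,nM,human,assayA
ibuprofen_like,OPRD_HUMAN_FRAG,310,nM,human,assayB
phenylpiperidine_like,OPRD_HUMAN_FRAG,12,nM,human,assayA
phenylpiperidine_like,DRD2_HUMAN_FRAG,45,uM,human,assayA
phenetole_like,DRD2_HUMAN_FRAG,85,nM,human,assayB
phenetole_like,DRD2_HUMAN_FRAG,95,nM,rat,assayB
ethanolpiperazine_like,OPRD_HUMAN_FRAG,22,uM,human,assayA
ethanolpiperazine_like,DRD2_HUMAN_FRAG,380,nM,human,assayA
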