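CC(C)Cc1ccccc1C(=O)O ibuprofen_like
CN1CCC(CC1)c1ccccc1 phenylpiperidine_like
CCOc1ccccc1OCC phenetole_like
OCCN1CCN(CC1)CCC ethanolpiperazine_like
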