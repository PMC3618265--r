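>OPRD_HUMAN_FRAG synthetic delta-opioid-like fragment
MELVPSARAELQSSPLVNLSDAFPSAFPSAGANASGSPGARSASSLALAIAITALYSAVC
AVGLLGNVLVMFGIVRYTKLKTATNIYIFNLALADALATSTLPFQSAKYLMETWPFGELL
CKAVLSIDYYNMFTSIFTLTMMSVDRYIAVCHPVKALDFRTPAKAKLINICIWVLASGVG
>DRD2_HUMAN_FRAG synthetic dopamine-D2-like fragment
MDPLNLSWYDDDLERQNWSRPFNGSDGKADRPHYNYYATLLTLLIAVIVFGNVLVCMAVS
REKALQTTTNYLIVSLAVADLLVATLVMPWVVYLEVVGEWKFSRIHCDIFVTLDVMMCTA
SILNLCAISIDRYTAVAMPMLYNTRYSSKRRVTVMISIVWVLSFTISCPLLFGLNNADQN
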