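# Co-repressor-interacting short linear motif patterns. Editable config:
# regexes below are literature-consensus approximations of the named ELM
# classes; substitute patterns from an ELM release (elm.eu.org) to match a
# specific database version. class_p is the pattern's reported class
# probability cutoff, recorded per match, not computed.
pattern_id	regex	cor_label	class_p
LIG_EH1_1	F.I..[IL][ILMV]	Groucho	2e-04
LIG_WRPW_2	[WF]RP[WY]	Groucho	2e-04
LIG_CtBP_PxDLS_1	P.DLS	CtBP	2e-04
LIG_Sin3_1	AA..[LV]	Sin3A	2e-04
LIG_HCF-1_HBM_1	[DE]H.Y	HCF	2e-04
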