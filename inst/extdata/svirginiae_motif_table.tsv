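# Conserved-domain comparison table for the 33 putative CYPs of
# Streptomyces virginiae IBL14: printed I-helix, K-helix and heme-binding
# region strings (markup stripped; empty cell = reported "Unidentified").
# heme_strict = 0 marks the five proteins reported as not strictly
# following the GXXXCXG heme-binding motif.
id	i_helix	k_helix	heme_region	heme_strict	accession
Svu001		ETLR	FLPFGAGPRHCVG	1	JX119062
Svu002			LRVGVDRRLCCG	0	
Svu003	GLDTT	ELLR	HLGFGHGIHQCLG	1	JX119063
Svu004	GHETT	ESLR	HLGFGHGIHQCLG	1	JX119064
Svu005	GHETT	ELMR	HLAFGFGIHQCLG	1	JX119065
Svh01	GFDTT	ELLR	HLAFSHGIHQCLG	1	EF646279
Svu006	GHETT	EMLR	HIAFGHGLHYCLG	1	JX119066
Svu007	GHETT	ELLR	HLGFGHGVHHCLG	1	JX119067
Svu008	GHETT	EMLR	HLAFGHGLHFCIG	1	JX119068
Svu009	GHKTT	EMQR	HLGFGYGAHYCLG	1	JX119069
Svu010	GHETT	EMLR	HLAFGHGIHFCIG	1	JX119070
Svu011	GHEAT	ELMR	HLTFGAGIHYCLG	1	JX119071
Svu012	GFETT	ELLR	HLGYGHGIHYCLG	1	JX119072
Svu013	GSETV	ELFR	HLALGHGVHYCLG	1	JX119073
Svu014	GHETT	ELLR	HLAFGHGVHRCLG	1	JX119074
Svu015	FAPTT	EVVR	QLSFGIGVHSCLG	1	JX119075
Svu016	GYHTT	EALR	HLAFGAGIHFCLG	1	JX119076
Svu017	GFLTT	EGLR	HVAFGYGPHACPG	1	JX119077
Svu018	GVIST	ELLR	HFSFGGGSHYCPA	0	JX119078
Svu019	GVETT	EMIR	HLGFGGGGPHFCLG	1	JX119079
Svu020	GHETT	ELLR	HLGLGSGIHSCFG	1	JX119080
Svu021	TWFTT	EVRR	ELIAQGGGNARTGHRCPG	0	JX119081
Svu022	GHETT	ETLR	HISFGHGPHVCPG	1	JX119082
Svu023	GHQPT	EVLW	FSFGHGEHRCPFPA	0	JX119083
Svu024	AFETT	EQILW	SHLAFSSGPHECPG	1	JX119084
Svu025			HLALGIGPHVCMG	1	JX119085
Svu026	GNETT	EVLR	HLALGSGPHYCLG	1	JX119086
Svu027	GNETT	EIVR	HLGFGGGGPHFCLG	1	JX119087
Svu028	GNDTV	ELLR	HVSFGDGPHVCLG	1	JX119088
Svu029	AHETT	ETLR	AFMPFGGGPRTCLG	1	JX119089
Svu030	GHETT	EAMR	AWFPFGGGPRACIG	1	JX119090
Svu031	GHETT	ETLR	AYLPFGIGPGPAWARSSRCGS	0	
Svu032	ANVTT	EGLR	RHGAFGFGPHFCIG	1	JX119091
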