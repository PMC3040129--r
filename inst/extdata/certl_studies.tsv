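# Microarray studies of the endometrial window of implantation pooled in the consensus.
# discloses_down = FALSE: study's down-regulated transcripts are not public, so it
# cannot vote on down-regulation.
study_id	platform	fold_change_cutoff	n_up	n_down	discloses_down
Kao2002	Affymetrix Hu95A	2	156	377	TRUE
Carson2002	Affymetrix Hu95A	2	323	370	TRUE
Borthwick2003	Affymetrix Hu95A-E	2	90	46	TRUE
Riesewijk2003	Affymetrix Hu95A	3	153	58	TRUE
Mirkin2005	Affymetrix HG_U95Av2	2	49	58	TRUE
Talbi2006	Affymetrix HG-U133 plus 2.0	1.5	1415	1463	TRUE
Haouzi2009	Affymetrix HG-U133 plus 2.0	2	945	67	FALSE
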