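# Direction calls underlying the consensus endometrial receptivity transcript list,
# transcribed from the published cross-study comparison tables (arrow = call, blank = absent).
# gene_id: UniGene cluster ID. One row per (study, gene) call.
study_id	gene_id	symbol	direction
Kao2002	Hs.1012	C4BPA	up
Carson2002	Hs.1012	C4BPA	up
Borthwick2003	Hs.1012	C4BPA	up
Riesewijk2003	Hs.1012	C4BPA	up
Talbi2006	Hs.1012	C4BPA	up
Haouzi2009	Hs.1012	C4BPA	up
Kao2002	Hs.313	SPP1	up
Carson2002	Hs.313	SPP1	up
Borthwick2003	Hs.313	SPP1	up
Riesewijk2003	Hs.313	SPP1	up
Mirkin2005	Hs.313	SPP1	up
Talbi2006	Hs.313	SPP1	up
Kao2002	Hs.522555	APOD	up
Carson2002	Hs.522555	APOD	up
Borthwick2003	Hs.522555	APOD	up
Riesewijk2003	Hs.522555	APOD	up
Talbi2006	Hs.522555	APOD	up
Kao2002	Hs.126517	CD55	up
Borthwick2003	Hs.126517	CD55	up
Riesewijk2003	Hs.126517	CD55	up
Mirkin2005	Hs.126517	CD55	up
Talbi2006	Hs.126517	CD55	up
Kao2002	Hs.155597	CFD	up
Carson2002	Hs.155597	CFD	up
Borthwick2003	Hs.155597	CFD	up
Riesewijk2003	Hs.155597	CFD	up
Talbi2006	Hs.155597	CFD	up
Kao2002	Hs.647036	CLDN4	up
Carson2002	Hs.647036	CLDN4	up
Borthwick2003	Hs.647036	CLDN4	up
Riesewijk2003	Hs.647036	CLDN4	up
Talbi2006	Hs.647036	CLDN4	up
Kao2002	Hs.40499	DKK1	up
Carson2002	Hs.40499	DKK1	up
Borthwick2003	Hs.40499	DKK1	up
Riesewijk2003	Hs.40499	DKK1	up
Talbi2006	Hs.40499	DKK1	up
Kao2002	Hs.519601	ID4	up
Carson2002	Hs.519601	ID4	up
Riesewijk2003	Hs.519601	ID4	up
Mirkin2005	Hs.519601	ID4	up
Haouzi2009	Hs.519601	ID4	up
Kao2002	Hs.654378	IL15	up
Carson2002	Hs.654378	IL15	up
Riesewijk2003	Hs.654378	IL15	up
Mirkin2005	Hs.654378	IL15	up
Talbi2006	Hs.654378	IL15	up
Kao2002	Hs.186486	MAP3K5	up
Carson2002	Hs.186486	MAP3K5	up
Borthwick2003	Hs.186486	MAP3K5	up
Riesewijk2003	Hs.186486	MAP3K5	up
Mirkin2005	Hs.186486	MAP3K5	up
Kao2002	Hs.511605	ANXA2	up
Carson2002	Hs.511605	ANXA2	up
Riesewijk2003	Hs.511605	ANXA2	up
Talbi2006	Hs.511605	ANXA2	up
Kao2002	Hs.422986	ANXA4	up
Riesewijk2003	Hs.422986	ANXA4	up
Mirkin2005	Hs.422986	ANXA4	up
Talbi2006	Hs.422986	ANXA4	up
Kao2002	Hs.524224	C1R	up
Borthwick2003	Hs.524224	C1R	up
Mirkin2005	Hs.524224	C1R	up
Talbi2006	Hs.524224	C1R	up
Kao2002	Hs.80409	GADD45A	up
Borthwick2003	Hs.80409	GADD45A	up
Riesewijk2003	Hs.80409	GADD45A	up
Mirkin2005	Hs.80409	GADD45A	up
Carson2002	Hs.386567	GBP2	up
Borthwick2003	Hs.386567	GBP2	up
Riesewijk2003	Hs.386567	GBP2	up
Talbi2006	Hs.386567	GBP2	up
Kao2002	Hs.183109	MAOA	up
Borthwick2003	Hs.183109	MAOA	up
Riesewijk2003	Hs.183109	MAOA	up
Mirkin2005	Hs.183109	MAOA	up
Kao2002	Hs.532325	PAEP	up
Borthwick2003	Hs.532325	PAEP	up
Riesewijk2003	Hs.532325	PAEP	up
Haouzi2009	Hs.532325	PAEP	up
Borthwick2003	Hs.384598	SERPING1	up
Riesewijk2003	Hs.384598	SERPING1	up
Mirkin2005	Hs.384598	SERPING1	up
Talbi2006	Hs.384598	SERPING1	up
Riesewijk2003	Hs.1584	COMP	up
Talbi2006	Hs.1584	COMP	up
Haouzi2009	Hs.1584	COMP	up
Borthwick2003	Hs.558314	CP	up
Riesewijk2003	Hs.558314	CP	up
Talbi2006	Hs.558314	CP	up
Riesewijk2003	Hs.368912	DPP4	up
Talbi2006	Hs.368912	DPP4	up
Haouzi2009	Hs.368912	DPP4	up
Kao2002	Hs.446392	DYNLT3	up
Borthwick2003	Hs.446392	DYNLT3	up
Riesewijk2003	Hs.446392	DYNLT3	up
Carson2002	Hs.198862	FBLN2	up
Riesewijk2003	Hs.198862	FBLN2	up
Talbi2006	Hs.198862	FBLN2	up
Carson2002	Hs.433300	FCER1G	up
Riesewijk2003	Hs.433300	FCER1G	up
Talbi2006	Hs.433300	FCER1G	up
Kao2002	Hs.432132	G0S2	up
Borthwick2003	Hs.432132	G0S2	up
Riesewijk2003	Hs.432132	G0S2	up
Borthwick2003	Hs.2681	GAST	up
Riesewijk2003	Hs.2681	GAST	up
Talbi2006	Hs.2681	GAST	up
Kao2002	Hs.616962	GDF15	up
Carson2002	Hs.616962	GDF15	up
Borthwick2003	Hs.616962	GDF15	up
Carson2002	Hs.105806	GNLY	up
Riesewijk2003	Hs.105806	GNLY	up
Talbi2006	Hs.105806	GNLY	up
Riesewijk2003	Hs.386793	GPX3	up
Talbi2006	Hs.386793	GPX3	up
Haouzi2009	Hs.386793	GPX3	up
Kao2002	Hs.497636	LAMB3	up
Riesewijk2003	Hs.497636	LAMB3	up
Talbi2006	Hs.497636	LAMB3	up
Kao2002	Hs.433391	MT1G	up
Carson2002	Hs.433391	MT1G	up
Borthwick2003	Hs.433391	MT1G	up
Carson2002	Hs.262857	PRUNE2	up
Borthwick2003	Hs.262857	PRUNE2	up
Riesewijk2003	Hs.262857	PRUNE2	up
Riesewijk2003	Hs.50223	RBP4	up
Talbi2006	Hs.50223	RBP4	up
Haouzi2009	Hs.50223	RBP4	up
Carson2002	Hs.654444	S100A4	up
Riesewijk2003	Hs.654444	S100A4	up
Talbi2006	Hs.654444	S100A4	up
Riesewijk2003	Hs.2962	S100P	up
Talbi2006	Hs.2962	S100P	up
Haouzi2009	Hs.2962	S100P	up
Riesewijk2003	Hs.517070	SLPI	up
Mirkin2005	Hs.517070	SLPI	up
Talbi2006	Hs.517070	SLPI	up
Riesewijk2003	Hs.517033	TGM2	up
Mirkin2005	Hs.517033	TGM2	up
Talbi2006	Hs.517033	TGM2	up
Riesewijk2003	Hs.525607	TNFAIP2	up
Mirkin2005	Hs.525607	TNFAIP2	up
Talbi2006	Hs.525607	TNFAIP2	up
Riesewijk2003	Hs.695930	VCAN	up
Mirkin2005	Hs.695930	VCAN	up
Talbi2006	Hs.695930	VCAN	up
Kao2002	Hs.2157	WAS	up
Carson2002	Hs.2157	WAS	up
Riesewijk2003	Hs.2157	WAS	up
Kao2002	Hs.522484	OLFM1	down
Carson2002	Hs.522484	OLFM1	down
Borthwick2003	Hs.522484	OLFM1	down
Riesewijk2003	Hs.522484	OLFM1	down
Talbi2006	Hs.522484	OLFM1	down
Kao2002	Hs.23960	CCNB1	down
Carson2002	Hs.23960	CCNB1	down
Riesewijk2003	Hs.23960	CCNB1	down
Talbi2006	Hs.23960	CCNB1	down
Kao2002	Hs.405662	CRABP2	down
Carson2002	Hs.405662	CRABP2	down
Borthwick2003	Hs.405662	CRABP2	down
Talbi2006	Hs.405662	CRABP2	down
Kao2002	Hs.1408	EDN3	down
Carson2002	Hs.1408	EDN3	down
Riesewijk2003	Hs.1408	EDN3	down
Talbi2006	Hs.1408	EDN3	down
Kao2002	Hs.264887	FGFR1	down
Carson2002	Hs.264887	FGFR1	down
Borthwick2003	Hs.264887	FGFR1	down
Talbi2006	Hs.264887	FGFR1	down
Kao2002	Hs.424414	MSX1	down
Riesewijk2003	Hs.424414	MSX1	down
Mirkin2005	Hs.424414	MSX1	down
Talbi2006	Hs.424414	MSX1	down
Kao2002	Hs.89404	MSX2	down
Carson2002	Hs.89404	MSX2	down
Riesewijk2003	Hs.89404	MSX2	down
Talbi2006	Hs.89404	MSX2	down
Carson2002	Hs.523852	CCND1	down
Mirkin2005	Hs.523852	CCND1	down
Talbi2006	Hs.523852	CCND1	down
Carson2002	Hs.524947	CDC20	down
Riesewijk2003	Hs.524947	CDC20	down
Talbi2006	Hs.524947	CDC20	down
Kao2002	Hs.1594	CENPA	down
Carson2002	Hs.1594	CENPA	down
Riesewijk2003	Hs.1594	CENPA	down
Carson2002	Hs.83758	CKS2	down
Mirkin2005	Hs.83758	CKS2	down
Talbi2006	Hs.83758	CKS2	down
Kao2002	Hs.530904	CSRP2	down
Riesewijk2003	Hs.530904	CSRP2	down
Talbi2006	Hs.530904	CSRP2	down
Kao2002	Hs.367725	GATA2	down
Borthwick2003	Hs.367725	GATA2	down
Mirkin2005	Hs.367725	GATA2	down
Carson2002	Hs.596913	HPGD	down
Riesewijk2003	Hs.596913	HPGD	down
Talbi2006	Hs.596913	HPGD	down
Carson2002	Hs.654504	IHH	down
Borthwick2003	Hs.654504	IHH	down
Talbi2006	Hs.654504	IHH	down
Carson2002	Hs.438720	MCM7	down
Borthwick2003	Hs.438720	MCM7	down
Mirkin2005	Hs.438720	MCM7	down
Kao2002	Hs.75823	MLLT11	down
Carson2002	Hs.75823	MLLT11	down
Borthwick2003	Hs.75823	MLLT11	down
Carson2002	Hs.143751	MMP11	down
Borthwick2003	Hs.143751	MMP11	down
Talbi2006	Hs.143751	MMP11	down
Kao2002	Hs.2256	MMP7	down
Carson2002	Hs.2256	MMP7	down
Borthwick2003	Hs.2256	MMP7	down
Kao2002	Hs.658169	SFRP4	down
Carson2002	Hs.658169	SFRP4	down
Borthwick2003	Hs.658169	SFRP4	down
Carson2002	Hs.182231	TRH	down
Borthwick2003	Hs.182231	TRH	down
Riesewijk2003	Hs.182231	TRH	down
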