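persister	SYNTHETIC placeholder for the chemotherapy persister-cell signature; substitute the published list	PERSISTER.SYN01	PERSISTER.SYN02	PERSISTER.SYN03	PERSISTER.SYN04	PERSISTER.SYN05	PERSISTER.SYN06	PERSISTER.SYN07	PERSISTER.SYN08	PERSISTER.SYN09	PERSISTER.SYN10	PERSISTER.SYN11	PERSISTER.SYN12	PERSISTER.SYN13	PERSISTER.SYN14	PERSISTER.SYN15	PERSISTER.SYN16	PERSISTER.SYN17	PERSISTER.SYN18	PERSISTER.SYN19	PERSISTER.SYN20	PERSISTER.SYN21	PERSISTER.SYN22	PERSISTER.SYN23	PERSISTER.SYN24	PERSISTER.SYN25	PERSISTER.SYN26	PERSISTER.SYN27	PERSISTER.SYN28	PERSISTER.SYN29	PERSISTER.SYN30
MBS	SYNTHETIC placeholder for the metastatic burden signature; substitute the published list	MBS.SYN01	MBS.SYN02	MBS.SYN03	MBS.SYN04	MBS.SYN05	MBS.SYN06	MBS.SYN07	MBS.SYN08	MBS.SYN09	MBS.SYN10	MBS.SYN11	MBS.SYN12	MBS.SYN13	MBS.SYN14	MBS.SYN15	MBS.SYN16	MBS.SYN17	MBS.SYN18	MBS.SYN19	MBS.SYN20	MBS.SYN21	MBS.SYN22	MBS.SYN23	MBS.SYN24	MBS.SYN25
EMP	SYNTHETIC placeholder for the 26-gene epithelial-mesenchymal plasticity signature; substitute the published list	EMP.SYN01	EMP.SYN02	EMP.SYN03	EMP.SYN04	EMP.SYN05	EMP.SYN06	EMP.SYN07	EMP.SYN08	EMP.SYN09	EMP.SYN10	EMP.SYN11	EMP.SYN12	EMP.SYN13	EMP.SYN14	EMP.SYN15	EMP.SYN16	EMP.SYN17	EMP.SYN18	EMP.SYN19	EMP.SYN20	EMP.SYN21	EMP.SYN22	EMP.SYN23	EMP.SYN24	EMP.SYN25	EMP.SYN26
micrometastasis	SYNTHETIC placeholder for the micrometastasis signature; substitute the published list	MICROMET.SYN01	MICROMET.SYN02	MICROMET.SYN03	MICROMET.SYN04	MICROMET.SYN05	MICROMET.SYN06	MICROMET.SYN07	MICROMET.SYN08	MICROMET.SYN09	MICROMET.SYN10	MICROMET.SYN11	MICROMET.SYN12	MICROMET.SYN13	MICROMET.SYN14	MICROMET.SYN15	MICROMET.SYN16	MICROMET.SYN17	MICROMET.SYN18	MICROMET.SYN19	MICROMET.SYN20
RTS	SYNTHETIC placeholder for the residual tumour signature; substitute the published list	RTS.SYN01	RTS.SYN02	RTS.SYN03	RTS.SYN04	RTS.SYN05	RTS.SYN06	RTS.SYN07	RTS.SYN08	RTS.SYN09	RTS.SYN10	RTS.SYN11	RTS.SYN12	RTS.SYN13	RTS.SYN14	RTS.SYN15	RTS.SYN16	RTS.SYN17	RTS.SYN18	RTS.SYN19	RTS.SYN20	RTS.SYN21	RTS.SYN22	RTS.SYN23	RTS.SYN24	RTS.SYN25	RTS.SYN26	RTS.SYN27	RTS.SYN28	RTS.SYN29	RTS.SYN30	RTS.SYN31	RTS.SYN32	RTS.SYN33	RTS.SYN34	RTS.SYN35	RTS.SYN36	RTS.SYN37	RTS.SYN38	RTS.SYN39	RTS.SYN40
PS	SYNTHETIC placeholder for the prognostic signature; substitute the published list	PS.SYN01	PS.SYN02	PS.SYN03	PS.SYN04	PS.SYN05	PS.SYN06	PS.SYN07	PS.SYN08	PS.SYN09	PS.SYN10	PS.SYN11	PS.SYN12	PS.SYN13	PS.SYN14	PS.SYN15	PS.SYN16	PS.SYN17	PS.SYN18	PS.SYN19	PS.SYN20	PS.SYN21	PS.SYN22	PS.SYN23	PS.SYN24	PS.SYN25	PS.SYN26	PS.SYN27	PS.SYN28	PS.SYN29	PS.SYN30	PS.SYN31	PS.SYN32	PS.SYN33	PS.SYN34	PS.SYN35
CIN70	SYNTHETIC placeholder for the 70-gene chromosomal instability signature; substitute the published list	CIN70.SYN01	CIN70.SYN02	CIN70.SYN03	CIN70.SYN04	CIN70.SYN05	CIN70.SYN06	CIN70.SYN07	CIN70.SYN08	CIN70.SYN09	CIN70.SYN10	CIN70.SYN11	CIN70.SYN12	CIN70.SYN13	CIN70.SYN14	CIN70.SYN15	CIN70.SYN16	CIN70.SYN17	CIN70.SYN18	CIN70.SYN19	CIN70.SYN20	CIN70.SYN21	CIN70.SYN22	CIN70.SYN23	CIN70.SYN24	CIN70.SYN25	CIN70.SYN26	CIN70.SYN27	CIN70.SYN28	CIN70.SYN29	CIN70.SYN30	CIN70.SYN31	CIN70.SYN32	CIN70.SYN33	CIN70.SYN34	CIN70.SYN35	CIN70.SYN36	CIN70.SYN37	CIN70.SYN38	CIN70.SYN39	CIN70.SYN40	CIN70.SYN41	CIN70.SYN42	CIN70.SYN43	CIN70.SYN44	CIN70.SYN45	CIN70.SYN46	CIN70.SYN47	CIN70.SYN48	CIN70.SYN49	CIN70.SYN50	CIN70.SYN51	CIN70.SYN52	CIN70.SYN53	CIN70.SYN54	CIN70.SYN55	CIN70.SYN56	CIN70.SYN57	CIN70.SYN58	CIN70.SYN59	CIN70.SYN60	CIN70.SYN61	CIN70.SYN62	CIN70.SYN63	CIN70.SYN64	CIN70.SYN65	CIN70.SYN66	CIN70.SYN67	CIN70.SYN68	CIN70.SYN69	CIN70.SYN70
p53_mut_vs_wt	SYNTHETIC placeholder for the p53 mutant-vs-wild-type signature; substitute the published list	P53SIG.SYN01	P53SIG.SYN02	P53SIG.SYN03	P53SIG.SYN04	P53SIG.SYN05	P53SIG.SYN06	P53SIG.SYN07	P53SIG.SYN08	P53SIG.SYN09	P53SIG.SYN10	P53SIG.SYN11	P53SIG.SYN12	P53SIG.SYN13	P53SIG.SYN14	P53SIG.SYN15	P53SIG.SYN16	P53SIG.SYN17	P53SIG.SYN18	P53SIG.SYN19	P53SIG.SYN20	P53SIG.SYN21	P53SIG.SYN22	P53SIG.SYN23	P53SIG.SYN24	P53SIG.SYN25	P53SIG.SYN26	P53SIG.SYN27	P53SIG.SYN28	P53SIG.SYN29	P53SIG.SYN30
RPS	Recombination proficiency score gene set (RIF1, PARI, RAD51, XRCC5/Ku80); scaled-negsum recipe	RIF1	PARI	RAD51	XRCC5
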