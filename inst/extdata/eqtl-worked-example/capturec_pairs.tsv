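sentinel_rsid	gene_symbol	source_label
rsE001	ANKS1A	shared_with_eqtl
rsE002	C6orf106	shared_with_eqtl
rsE003	RMI2	shared_with_eqtl
rsE004	SOCS1	shared_with_eqtl
rsE005	PXK	shared_with_eqtl
rsE006	UHRF1BP1	shared_with_eqtl
rsE007	LYST	shared_with_eqtl
rsE008	NADSYN1	shared_with_eqtl
rsE009	DHCR7	shared_with_eqtl
rsE010	C15orf39	shared_with_eqtl
rsE011	MPI	shared_with_eqtl
rsE012	CSK	shared_with_eqtl
rsE013	ULK3	shared_with_eqtl
rsE014	FAM219B	shared_with_eqtl
rsC001	CAPTURECONLY01	synthetic_placeholder
rsC002	CAPTURECONLY02	synthetic_placeholder
rsC003	CAPTURECONLY03	synthetic_placeholder
rsC004	CAPTURECONLY04	synthetic_placeholder
rsC005	CAPTURECONLY05	synthetic_placeholder
rsC006	CAPTURECONLY06	synthetic_placeholder
rsC007	CAPTURECONLY07	synthetic_placeholder
rsC008	CAPTURECONLY08	synthetic_placeholder
rsC009	CAPTURECONLY09	synthetic_placeholder
rsC010	CAPTURECONLY10	synthetic_placeholder
rsC011	CAPTURECONLY11	synthetic_placeholder
rsC012	CAPTURECONLY12	synthetic_placeholder
rsC013	CAPTURECONLY13	synthetic_placeholder
rsC014	CAPTURECONLY14	synthetic_placeholder
rsC015	CAPTURECONLY15	synthetic_placeholder
rsC016	CAPTURECONLY16	synthetic_placeholder
rsC017	CAPTURECONLY17	synthetic_placeholder
rsC018	CAPTURECONLY18	synthetic_placeholder
rsC019	CAPTURECONLY19	synthetic_placeholder
rsC020	CAPTURECONLY20	synthetic_placeholder
rsC021	CAPTURECONLY21	synthetic_placeholder
rsC022	CAPTURECONLY22	synthetic_placeholder
rsC023	CAPTURECONLY23	synthetic_placeholder
rsC024	CAPTURECONLY24	synthetic_placeholder
rsC025	CAPTURECONLY25	synthetic_placeholder
rsC026	CAPTURECONLY26	synthetic_placeholder
rsC027	CAPTURECONLY27	synthetic_placeholder
rsC028	CAPTURECONLY28	synthetic_placeholder
rsC029	CAPTURECONLY29	synthetic_placeholder
rsC030	CAPTURECONLY30	synthetic_placeholder
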