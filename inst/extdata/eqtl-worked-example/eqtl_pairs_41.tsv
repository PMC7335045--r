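sentinel_rsid	gene_symbol	source_label
rsE001	ANKS1A	shared_with_capturec
rsE002	C6orf106	shared_with_capturec
rsE003	RMI2	shared_with_capturec
rsE004	SOCS1	shared_with_capturec
rsE005	PXK	shared_with_capturec
rsE006	UHRF1BP1	shared_with_capturec
rsE007	LYST	shared_with_capturec
rsE008	NADSYN1	shared_with_capturec
rsE009	DHCR7	shared_with_capturec
rsE010	C15orf39	shared_with_capturec
rsE011	MPI	shared_with_capturec
rsE012	CSK	shared_with_capturec
rsE013	ULK3	shared_with_capturec
rsE014	FAM219B	shared_with_capturec
rsE015	EQTLONLY01	synthetic_placeholder
rsE016	EQTLONLY02	synthetic_placeholder
rsE017	EQTLONLY03	synthetic_placeholder
rsE018	EQTLONLY04	synthetic_placeholder
rsE019	EQTLONLY05	synthetic_placeholder
rsE020	EQTLONLY06	synthetic_placeholder
rsE021	EQTLONLY07	synthetic_placeholder
rsE022	EQTLONLY08	synthetic_placeholder
rsE023	EQTLONLY09	synthetic_placeholder
rsE024	EQTLONLY10	synthetic_placeholder
rsE025	EQTLONLY11	synthetic_placeholder
rsE026	EQTLONLY12	synthetic_placeholder
rsE027	EQTLONLY13	synthetic_placeholder
rsE028	EQTLONLY14	synthetic_placeholder
rsE029	EQTLONLY15	synthetic_placeholder
rsE030	EQTLONLY16	synthetic_placeholder
rsE031	EQTLONLY17	synthetic_placeholder
rsE032	EQTLONLY18	synthetic_placeholder
rsE033	EQTLONLY19	synthetic_placeholder
rsE034	EQTLONLY20	synthetic_placeholder
rsE035	EQTLONLY21	synthetic_placeholder
rsE036	EQTLONLY22	synthetic_placeholder
rsE037	EQTLONLY23	synthetic_placeholder
rsE038	EQTLONLY24	synthetic_placeholder
rsE039	EQTLONLY25	synthetic_placeholder
rsE040	EQTLONLY26	synthetic_placeholder
rsE041	EQTLONLY27	synthetic_placeholder
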