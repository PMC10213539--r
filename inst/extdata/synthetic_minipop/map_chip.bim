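chrom	marker	pos	a1	a2
chr01	snp00002	30000	A	B
chr01	snp00003	45000	A	B
chr01	snp00004	60000	A	B
chr01	snp00006	90000	A	B
chr01	snp00009	135000	A	B
chr01	snp00013	195000	A	B
chr01	snp00015	225000	A	B
chr01	snp00018	270000	A	B
chr02	snp00021	15000	A	B
chr02	snp00022	30000	A	B
chr02	snp00030	150000	A	B
chr02	snp00031	165000	A	B
chr02	snp00032	180000	A	B
chr02	snp00033	195000	A	B
chr02	snp00035	225000	A	B
chr02	snp00036	240000	A	B
chr02	snp00037	255000	A	B
chr02	snp00038	270000	A	B
chr03	snp00045	75000	A	B
chr03	snp00046	90000	A	B
chr03	snp00048	120000	A	B
chr03	snp00049	135000	A	B
chr03	snp00050	150000	A	B
chr03	snp00052	180000	A	B
chr03	snp00057	255000	A	B
chr04	snp00062	30000	A	B
chr04	snp00066	90000	A	B
chr04	snp00072	180000	A	B
chr04	snp00074	210000	A	B
chr04	snp00075	225000	A	B
chr04	snp00078	270000	A	B
chr04	snp00079	285000	A	B
chr05	snp00083	45000	A	B
chr05	snp00085	75000	A	B
chr05	snp00087	105000	A	B
chr05	snp00089	135000	A	B
chr05	snp00090	150000	A	B
chr05	snp00092	180000	A	B
chr05	snp00093	195000	A	B
chr05	snp00096	240000	A	B
chr05	snp00098	270000	A	B
chr05	snp00100	3e+05	A	B
chr06	snp00104	60000	A	B
chr06	snp00107	105000	A	B
chr06	snp00109	135000	A	B
chr06	snp00110	150000	A	B
chr06	snp00113	195000	A	B
chr06	snp00118	270000	A	B
chr07	snp00122	30000	A	B
chr07	snp00123	45000	A	B
chr07	snp00124	60000	A	B
chr07	snp00128	120000	A	B
chr07	snp00129	135000	A	B
chr07	snp00131	165000	A	B
chr07	snp00132	180000	A	B
chr07	snp00134	210000	A	B
chr07	snp00139	285000	A	B
chr07	snp00140	3e+05	A	B
chr08	snp00142	30000	A	B
chr08	snp00143	45000	A	B
chr08	snp00147	105000	A	B
chr08	snp00149	135000	A	B
chr08	snp00150	150000	A	B
chr08	snp00152	180000	A	B
chr08	snp00153	195000	A	B
chr09	snp00162	30000	A	B
chr09	snp00164	60000	A	B
chr09	snp00166	90000	A	B
chr09	snp00167	105000	A	B
chr09	snp00168	120000	A	B
chr09	snp00170	150000	A	B
chr09	snp00174	210000	A	B
chr09	snp00176	240000	A	B
chr09	snp00177	255000	A	B
chr09	snp00178	270000	A	B
chr10	snp00182	30000	A	B
chr10	snp00184	60000	A	B
chr10	snp00189	135000	A	B
chr10	snp00191	165000	A	B
chr10	snp00193	195000	A	B
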