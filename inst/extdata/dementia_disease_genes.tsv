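disease	accession	symbol	marker
Alzheimer	P05067	APP	Tau
Alzheimer	P01023	A2M	Tau
Alzheimer	P49768	PSEN1	Tau
Alzheimer	Q6ZW49	PAXIP1	Tau
Alzheimer	P49810	PSEN2	Tau
Alzheimer	P29474	NOS3	Tau
Alzheimer	P05164	MPO	Tau
Alzheimer	Q92870	APBB2	Tau
Alzheimer	P02649	APOE	Tau
Alzheimer	P00749	PLAU	Tau
Alzheimer	Q30201	HFE	Tau
Alzheimer	Q92673	SORL1	Tau
Alzheimer	P12821	ACE	Tau
Alzheimer	Q13867	BLMH	Tau
Amyotrophic lateral sclerosis-Parkinsonism/Dementia complex	Q99497	PARK7	Tau
Dementia, familial, non-specific	Q9UQN3	CHMP2B	Tau
Dystonia-Parkinsonism	P21675	TAF1	Tau
Frontotemporal Dementia	Q13148	TARDBP	Tau
Frontotemporal Dementia	P10636	MAPT	Tau
Frontotemporal Dementia	P28799	GRN	Tau
Supranuclear palsy	P10636	MAPT	Tau
Prion	P04156	PRNP	Prion
Prion	P54259	ATN1	Prion
Prion	Q99574	SERPINI1	Prion
Prion	P01920	HLA-DQB1	Prion
Prion, Huntington disease-like 1	P04156	PRNP	Prion/Hungtintin
Huntington Disease	P42858	HTT	Hungtintin
Huntington disease-like 1	P04156	PRNP	Hungtintin
Huntington disease-like 2	Q8WXH2	JPH3	Hungtintin
Huntington disease-like-4	P20226	TPB	Hungtintin
Dementia, Lewy body	P37840	SNCA	Alpha-synuclein
Dementia, Lewy body	Q16143	SNCB	Alpha-synuclein
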