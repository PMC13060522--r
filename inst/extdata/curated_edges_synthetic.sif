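APP	pp	CLU
PSEN1	pp	APBA1
MAPT	pp	NTRK2
CLU	pp	MPO
MAPT	pp	CASP4
NCSTN	pp	CLU
PRKCG	pp	NTRK2
CLU	pp	HSD17B10
APOE	pp	CLU
PSEN1	pp	MAPT
CASP4	pp	GNB1
APP	pp	GNB2
CASP4	pp	MPO
PSEN1	pp	APP
MAPT	pp	APP
MAPT	pp	NTRK1
PSEN1	pp	APOE
APOE	pp	A2M
NTRK2	pp	UQCRC2
CLU	pp	CASP4
APP	pp	PRKCA
APP	pp	CTSC
APOE	pp	CTSD
PSEN1	pp	UQCRC2
CLU	pp	SERPINA3
APP	pp	APOE
GNB2	pp	UQCRC2
CTSC	pp	HSD17B10
CTSC	pp	CTSD
APP	pp	CASP4
A2M	pp	CTSD
APP	pp	MPO
MAPT	pp	APOE
NCSTN	pp	A2M
SERPINA3	pp	GNB2
PSEN1	pp	HSD17B10
PSEN1	pp	CLU
CTSD	pp	APBA1
PSEN1	pp	SERPINA3
MAPT	pp	APBA1
CLU	pp	CTSD
APOE	pp	CTSC
MAPT	pp	ABCA1
MAPT	pp	CTSD
APP	pp	NTRK2
PSEN1	pp	CASP4
PSEN1	pp	NCSTN
CTSD	pp	PRKCZ
CTSD	pp	GNB2
MAPT	pp	HSD17B10
PSEN1	pp	CTSC
GNB2	pp	NTRK2
SERPINA3	pp	APBA1
PSEN1	pp	GNB2
MAPT	pp	PRKCG
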