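family	class	roles	scope	is_lignocellulolytic_default	source
GH1	GH	cellulase_betaglucosidase,hemicellulase	microbiota	TRUE	reported
GH2	GH	hemicellulase	microbiota	TRUE	reported
GH3	GH	cellulase_betaglucosidase,hemicellulase	microbiota	TRUE	reported
GH5	GH	cellulase_endo,hemicellulase	microbiota	TRUE	reported
GH6	GH	cellulase_endo	microbiota	TRUE	reported
GH8	GH	cellulase_endo,hemicellulase	microbiota	TRUE	reported
GH9	GH	cellulase_endo	both	TRUE	reported
GH10	GH	hemicellulase	microbiota	TRUE	curated
GH11	GH	hemicellulase	microbiota	TRUE	curated
GH16	GH	hemicellulase	microbiota	TRUE	reported
GH26	GH	hemicellulase	microbiota	TRUE	reported
GH27	GH	hemicellulase	microbiota	TRUE	curated
GH29	GH	hemicellulase	microbiota	TRUE	curated
GH30	GH	hemicellulase	both	TRUE	reported
GH31	GH	hemicellulase	microbiota	TRUE	curated
GH35	GH	hemicellulase	microbiota	TRUE	reported
GH36	GH	hemicellulase	microbiota	TRUE	curated
GH39	GH	hemicellulase	microbiota	TRUE	curated
GH43	GH	hemicellulase	microbiota	TRUE	reported
GH44	GH	cellulase_endo	microbiota	TRUE	reported
GH48	GH	cellulase_endo	microbiota	TRUE	reported
GH51	GH	hemicellulase	microbiota	TRUE	curated
GH53	GH	hemicellulase	microbiota	TRUE	curated
GH67	GH	hemicellulase	microbiota	TRUE	curated
GH74	GH	cellulase_endo	microbiota	TRUE	reported
GH78	GH	hemicellulase	microbiota	TRUE	curated
GH94	GH	cellulase_phosphorylase	microbiota	TRUE	reported
GH95	GH	hemicellulase	microbiota	TRUE	curated
GH113	GH	hemicellulase	microbiota	TRUE	curated
GH115	GH	hemicellulase	microbiota	TRUE	curated
GH116	GH	cellulase_betaglucosidase	microbiota	TRUE	reported
GH127	GH	hemicellulase	microbiota	TRUE	curated
GH130	GH	hemicellulase	microbiota	TRUE	reported
CE1	CE	hemicellulase	microbiota	TRUE	reported
CE2	CE	hemicellulase	microbiota	TRUE	curated
CE3	CE	hemicellulase	microbiota	TRUE	reported
CE4	CE	hemicellulase	microbiota	TRUE	curated
CE5	CE	hemicellulase	microbiota	TRUE	curated
CE6	CE	hemicellulase	microbiota	TRUE	curated
CE7	CE	hemicellulase	microbiota	TRUE	curated
CE15	CE	hemicellulase	microbiota	TRUE	curated
AA1	AA	lme_laccase	both	TRUE	reported
AA3	AA	lme_cdh	both	TRUE	reported
AA10	AA	cellulase_lpmo	microbiota	TRUE	reported
AA15	AA	cellulase_lpmo	host	TRUE	reported
GH38	GH	hemicellulase	host	TRUE	reported
GH47	GH	hemicellulase	host	TRUE	reported
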