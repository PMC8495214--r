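organism	deg10	deg15	core
Acinetobacter sp. ADP1	0.83	0.87	TRUE
Burkholderia pseudomallei K96243	0.65	0.72	TRUE
Bacillus subtilis	0.87	0.90	TRUE
Burkholderia thailandensis E264	0.90	0.95	TRUE
Bacteroides thetaiotaomicron VPI-5482	0.72	0.70	TRUE
Escherichia coli K-12 substr MG1655	0.85	0.90	TRUE
Caulobacter crescentus NA1000	0.91	0.91	TRUE
Campylobacter jejuni	0.66	0.67	TRUE
Francisella tularensis novicida U112	0.75	0.81	TRUE
Haemophilus influenzae	0.53	0.65	TRUE
Helicobacter pylori 26695	0.59	0.67	TRUE
Mycoplasma genitalium	0.62	0.82	TRUE
Mycoplasma pulmonis	0.81	0.75	TRUE
Pseudomonas aeruginosa UCBPP-PA14	0.77	0.76	TRUE
Pseudomonas aeruginosa	0.67	0.81	TRUE
Porphyromonas gingivalis ATCC 33277	0.77	0.88	TRUE
Mycobacterium tuberculosis H37Rv	0.74	0.90	TRUE
Staphylococcus aureus NCTC 8325	0.82	0.92	TRUE
Staphylococcus aureus N315	0.85	0.70	TRUE
Shewanella oneidensis	0.88	0.80	TRUE
Streptococcus pneumoniae R6	0.72	0.92	TRUE
Streptococcus pyogenes NZ131	0.85	0.74	TRUE
Streptococcus sanguinis SK36	0.92	0.86	TRUE
Salmonella typhimurium LT2	0.70	0.95	TRUE
Sphingomonas wittichii RW1	0.82	0.72	TRUE
Salmonella enterica serovar Typhi Ty2	0.89	0.72	TRUE
Vibrio cholerae	0.63	0.85	TRUE
Acinetobacter baumannii ATCC 17978	0.69	0.79	FALSE
Burkholderia cenocepacia J2315	0.72	0.79	FALSE
Campylobacter jejuni 81176	0.78	0.82	FALSE
Mycobacterium tuberculosis H37Rv II	0.72	0.80	FALSE
Mycoplasma pneumoniae M129	0.81	0.72	FALSE
Ralstonia solanacearum GMI1000	0.79	0.78	FALSE
Rhodopseudomonas palustris CGA009	0.75	0.69	FALSE
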