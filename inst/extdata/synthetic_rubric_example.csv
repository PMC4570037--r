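"protocol_id","domain","keyword_id","text","weight","essential"
"EX-PROT-01","trial_design","parallel_group","two-arm parallel group",3,TRUE
"EX-PROT-01","trial_design","ratio_1_1","1:1 allocation ratio",2,TRUE
"EX-PROT-01","trial_design","superiority","superiority trial",2,FALSE
"EX-PROT-01","trial_design","protocol_changes","no important changes after commencement",1,FALSE
"EX-PROT-01","randomization","computer_generated","Computer generated",3,TRUE
"EX-PROT-01","randomization","blocks_of_4","blocks of 4",2,FALSE
"EX-PROT-01","randomization","ratio_1_1","1:1",1,FALSE
"EX-PROT-01","randomization","strat_site","stratification on site",2,TRUE
"EX-PROT-01","blinding","double_blind","double blind",3,TRUE
"EX-PROT-01","blinding","placebo_matched","matching placebo",2,FALSE
"EX-PROT-01","blinding","who_blinded","participants carers and assessors blinded",2,TRUE
"EX-PROT-01","participants","adults_18","adults aged 18 years or older",2,TRUE
"EX-PROT-01","participants","diagnosis_confirmed","diagnosis confirmed by imaging",3,TRUE
"EX-PROT-01","participants","exclusion_pregnancy","pregnant women excluded",1,FALSE
"EX-PROT-01","participants","recruitment_centres","recruited in 12 centres",1,FALSE
"EX-PROT-01","interventions","dose_10mg","10 mg orally",3,TRUE
"EX-PROT-01","interventions","once_daily","once daily",2,TRUE
"EX-PROT-01","interventions","duration_12w","for 12 weeks",2,FALSE
"EX-PROT-01","interventions","comparator_placebo","identical placebo",2,TRUE
"EX-PROT-01","outcomes","primary_6m","primary outcome at 6 months",3,TRUE
"EX-PROT-01","outcomes","scale_0_100","0 to 100 scale",2,TRUE
"EX-PROT-01","outcomes","assessor_central","centrally assessed",1,FALSE
"EX-PROT-01","outcomes","secondary_listed","secondary outcomes",1,FALSE
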