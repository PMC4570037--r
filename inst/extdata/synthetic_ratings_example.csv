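"protocol_id","domain","rater_id","keyword_id","present","flagged_missing"
"EX-PROT-01","trial_design","rater1","parallel_group",1,0
"EX-PROT-01","trial_design","rater1","ratio_1_1",1,0
"EX-PROT-01","trial_design","rater1","superiority",1,0
"EX-PROT-01","trial_design","rater1","protocol_changes",0,0
"EX-PROT-01","randomization","rater1","computer_generated",1,0
"EX-PROT-01","randomization","rater1","blocks_of_4",1,1
"EX-PROT-01","randomization","rater1","ratio_1_1",1,0
"EX-PROT-01","randomization","rater1","strat_site",1,0
"EX-PROT-01","blinding","rater1","double_blind",1,0
"EX-PROT-01","blinding","rater1","placebo_matched",0,0
"EX-PROT-01","blinding","rater1","who_blinded",1,0
"EX-PROT-01","participants","rater1","adults_18",1,0
"EX-PROT-01","participants","rater1","diagnosis_confirmed",1,0
"EX-PROT-01","participants","rater1","exclusion_pregnancy",0,0
"EX-PROT-01","participants","rater1","recruitment_centres",0,0
"EX-PROT-01","interventions","rater1","dose_10mg",1,0
"EX-PROT-01","interventions","rater1","once_daily",1,0
"EX-PROT-01","interventions","rater1","duration_12w",1,0
"EX-PROT-01","interventions","rater1","comparator_placebo",1,0
"EX-PROT-01","outcomes","rater1","primary_6m",1,0
"EX-PROT-01","outcomes","rater1","scale_0_100",1,0
"EX-PROT-01","outcomes","rater1","assessor_central",0,0
"EX-PROT-01","outcomes","rater1","secondary_listed",0,0
"EX-PROT-01","trial_design","rater2","parallel_group",1,0
"EX-PROT-01","trial_design","rater2","ratio_1_1",0,0
"EX-PROT-01","trial_design","rater2","superiority",1,0
"EX-PROT-01","trial_design","rater2","protocol_changes",0,0
"EX-PROT-01","randomization","rater2","computer_generated",1,0
"EX-PROT-01","randomization","rater2","blocks_of_4",1,1
"EX-PROT-01","randomization","rater2","ratio_1_1",1,0
"EX-PROT-01","randomization","rater2","strat_site",1,0
"EX-PROT-01","blinding","rater2","double_blind",1,0
"EX-PROT-01","blinding","rater2","placebo_matched",0,0
"EX-PROT-01","blinding","rater2","who_blinded",0,0
"EX-PROT-01","participants","rater2","adults_18",1,0
"EX-PROT-01","participants","rater2","diagnosis_confirmed",1,0
"EX-PROT-01","participants","rater2","exclusion_pregnancy",0,0
"EX-PROT-01","participants","rater2","recruitment_centres",0,0
"EX-PROT-01","interventions","rater2","dose_10mg",1,0
"EX-PROT-01","interventions","rater2","once_daily",1,0
"EX-PROT-01","interventions","rater2","duration_12w",1,0
"EX-PROT-01","interventions","rater2","comparator_placebo",1,0
"EX-PROT-01","outcomes","rater2","primary_6m",1,0
"EX-PROT-01","outcomes","rater2","scale_0_100",1,0
"EX-PROT-01","outcomes","rater2","assessor_central",0,0
"EX-PROT-01","outcomes","rater2","secondary_listed",0,0
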