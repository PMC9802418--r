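study_id,capsule_model,sb_duration_s,reached_colon,record_type,timestamp_s,lesion_type,traversed
example-01,SB3,14400,TRUE,lesion,2000,irregular_circular_ulcer,NA
example-01,SB3,14400,TRUE,lesion,3100,erosion,NA
example-01,SB3,14400,TRUE,lesion,5600,irregular_circular_ulcer,NA
example-02,SB3,13000,TRUE,lesion,900,erosion,NA
example-03,SB3,16000,TRUE,lesion,1500,longitudinal_large_ulcer_cobblestone,NA
example-03,SB3,16000,TRUE,lesion,6000,edema_redness,NA
example-03,SB3,16000,TRUE,lesion,9000,erosion,NA
example-03,SB3,16000,TRUE,lesion,14000,irregular_circular_ulcer,NA
example-03,SB3,16000,TRUE,stenosis,8000,NA,TRUE
example-04,SB3,11000,TRUE,none,NA,NA,NA
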