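respondent_id,group,role,sex,age_band,experience_band,qualification,academic
R01,EDr,Emergency Physician,Male,>55,16 years or more,Medical Degree,FALSE
R02,EDr,Emergency Physician,Male,35-54,16 years or more,Medical Degree,FALSE
R03,EDr,Emergency Physician,Male,>55,16 years or more,PhD/DN,TRUE
R04,SDr,Stroke Doctor,Male,>55,16 years or more,Medical Degree,FALSE
R05,SDr,Stroke Doctor,Male,35-54,16 years or more,PhD/DN,TRUE
R06,SDr,Stroke Doctor,Male,>55,16 years or more,PhD/DN,FALSE
R07,EN,Emergency Nurse Specialist,Female,35-54,16 years or more,Master's Degree,FALSE
R08,EN,Emergency Nurse Specialist,Female,35-54,16 years or more,Master's Degree,FALSE
R09,EN,Emergency Nurse Specialist,Male,<34,5-10 years,Bachelor's Degree,FALSE
R10,SN,Stroke Nurse Specialist,Female,35-54,16 years or more,Master's Degree,FALSE
R11,SN,Stroke Nurse Specialist,Female,>55,16 years or more,PhD/DN,FALSE
R12,SN,Stroke Nurse Specialist,Male,35-54,16 years or more,Master's Degree,FALSE
R13,BM,Bed Manager,Female,35-54,11-15 years,Master's Degree,FALSE
R14,BM,Bed Manager,Male,35-54,16 years or more,Master's Degree,FALSE
R15,SP,Speech Pathologist,Female,<34,5-10 years,Bachelor's Degree,FALSE
R16,SP,Speech Pathologist,Female,<34,5-10 years,Bachelor's Degree,FALSE
R17,SP,Speech Pathologist,Female,>55,11-15 years,PhD/DN,FALSE
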