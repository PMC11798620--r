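system,measure,unit,lower,upper,score
respiration,pao2_fio2_ratio,mmHg,400,Inf,0
respiration,pao2_fio2_ratio,mmHg,300,400,1
respiration,pao2_fio2_ratio,mmHg,200,300,2
respiration,pao2_fio2_ratio,mmHg,100,200,3
respiration,pao2_fio2_ratio,mmHg,0,100,4
coagulation,platelets,1e3_per_uL,150,Inf,0
coagulation,platelets,1e3_per_uL,100,150,1
coagulation,platelets,1e3_per_uL,50,100,2
coagulation,platelets,1e3_per_uL,20,50,3
coagulation,platelets,1e3_per_uL,0,20,4
liver,bilirubin,mg_per_dL,0,1.2,0
liver,bilirubin,mg_per_dL,1.2,2,1
liver,bilirubin,mg_per_dL,2,6,2
liver,bilirubin,mg_per_dL,6,12,3
liver,bilirubin,mg_per_dL,12,Inf,4
cardiovascular,mean_arterial_pressure,mmHg,70,Inf,0
cardiovascular,mean_arterial_pressure,mmHg,0,70,1
cns,glasgow_coma_scale,points,15,16,0
cns,glasgow_coma_scale,points,13,15,1
cns,glasgow_coma_scale,points,10,13,2
cns,glasgow_coma_scale,points,6,10,3
cns,glasgow_coma_scale,points,3,6,4
renal,creatinine,mg_per_dL,0,1.2,0
renal,creatinine,mg_per_dL,1.2,2,1
renal,creatinine,mg_per_dL,2,3.5,2
renal,creatinine,mg_per_dL,3.5,5,3
renal,creatinine,mg_per_dL,5,Inf,4
renal,urine_output,mL_per_day,500,Inf,0
renal,urine_output,mL_per_day,200,500,3
renal,urine_output,mL_per_day,0,200,4
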