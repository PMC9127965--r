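characteristic,block,type,validation_n,validation_mean,validation_sd,development_n,development_mean,development_sd
men_pct,subjects,proportion,20,50,NA,34,50,NA
age_y,subjects,continuous,20,24.3,1.98,34,23.2,2.11
height_cm,subjects,continuous,20,169.0,7.69,34,168.6,7.27
weight_kg,subjects,continuous,20,62.7,9.10,34,64.8,11.68
bmi_kg_m2,subjects,continuous,20,21.8,1.92,34,22.7,3.44
skeletal_muscle_kg,subjects,continuous,20,27.4,6.32,34,26.9,6.27
percent_body_fat,subjects,continuous,20,22.0,7.69,34,21.3,9.33
waist_hip_ratio,subjects,continuous,20,0.8,0.04,34,0.8,0.05
basal_metabolism_kcal,subjects,continuous,20,1431.9,221.15,34,1416.4,221.95
fasting_glucose_mg_dl,subjects,continuous,20,92.8,4.78,34,92.7,5.05
available_carbohydrate_g,events,continuous,192,37.9,17.65,239,47.6,20.32
fat_g,events,continuous,192,10.2,8.14,239,9.4,6.27
protein_g,events,continuous,192,8.5,5.81,239,11.6,6.47
fiber_g,events,continuous,192,2.8,2.86,239,4.6,3.34
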