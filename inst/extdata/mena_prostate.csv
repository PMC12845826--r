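# population_total: 47000000
# target_incidence: 0.000237
name,category,exposure_definition,prevalence,rr,rr_ci_low,rr_ci_high,rr_alt,rr_alt_ci_low,rr_alt_ci_high,alt_label
tobacco_smoking,behavioral,ever vs. never,0.25,1.42,1.20,1.68,NA,NA,NA,NA
obesity,behavioral,BMI >= 30 vs. < 25 kg/m2,0.30,1.12,1.06,1.19,NA,NA,NA,NA
physical_inactivity,behavioral,lowest vs. highest activity,0.40,1.18,1.08,1.29,NA,NA,NA,NA
high_dairy_intake,behavioral,highest vs. lowest intake,0.35,1.09,1.02,1.16,NA,NA,NA,NA
high_calcium_intake,behavioral,>= 1000 mg/day vs. < 500 mg/day,0.35,1.17,1.06,1.28,NA,NA,NA,NA
heavy_alcohol,behavioral,heavy vs. none,0.05,1.18,1.10,1.26,NA,NA,NA,NA
nitrate,environmental,drinking water above 50 mg/L,0.30,1.70,1.20,2.41,NA,NA,NA,NA
thms,environmental,drinking water THMs above 49 ug/L,0.35,1.15,0.95,1.40,NA,NA,NA,NA
arsenic,environmental,drinking water above 10 ug/L,0.18,1.18,1.06,1.30,NA,NA,NA,NA
lead,environmental,per study-specific increment (exceedance),0.18,1.04,1.02,1.05,NA,NA,NA,NA
selenium,environmental,per unit increase (protective),0.28,0.86,0.78,0.94,NA,NA,NA,NA
pm25,environmental,ambient air per 5 ug/m3 increase (exceedance),0.60,1.06,1.02,1.10,NA,NA,NA,NA
no2,environmental,ambient air per 10 ug/m3 increase (exceedance),0.60,1.04,1.01,1.07,NA,NA,NA,NA
diesel_exhaust,environmental,occupational 25th to 75th percentile cumulative exposure,0.02,1.24,0.96,1.61,1.27,0.80,2.01,75th to 95th percentile
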