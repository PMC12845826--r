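quantity,label,reported_percent
paf_closed,tobacco_smoking,9.5
paf_closed,obesity,3.5
paf_closed,physical_inactivity,6.7
paf_closed,high_dairy_intake,3.1
paf_closed,high_calcium_intake,5.6
paf_closed,heavy_alcohol,0.9
paf_closed,nitrate,17.4
paf_closed,thms,5.0
paf_closed,arsenic,3.1
paf_closed,lead,0.7
paf_closed,selenium,-4.1
paf_closed,pm25,3.5
paf_closed,no2,2.3
paf_closed,diesel_exhaust,0.5
paf_closed,diesel_exhaust_alt,0.5
paf_cohort,tobacco_smoking,9.5
paf_cohort,obesity,3.5
paf_cohort,physical_inactivity,6.7
paf_cohort,high_dairy_intake,3.0
paf_cohort,high_calcium_intake,5.6
paf_cohort,heavy_alcohol,0.9
paf_cohort,nitrate,17.4
paf_cohort,thms,5.0
paf_cohort,arsenic,3.1
paf_cohort,lead,0.7
paf_cohort,selenium,-4.1
paf_cohort,pm25,3.5
paf_cohort,no2,2.4
paf_cohort,diesel_exhaust,0.5
paf_cohort,diesel_exhaust_alt,0.5
joint_paf,behavioral,25.8
joint_paf,environmental,26.6
joint_paf,all,45.5
pif,thms,1.5
pif,physical_inactivity,1.7
pif,nitrate,5.8
pif,tobacco_smoking,3.8
pif,combined,12.1
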