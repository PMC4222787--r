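id,label,cluster,domain,status,target_pop_2010,recipient_pop_2010,unit_cost,initial,best,units,cvd_split,account
bp_care,Use of quality BP care,care_est,care,established,78.7,39.4,440,60,100,percent,both,risk_mgmt
chol_care,Use of quality cholesterol care,care_est,care,established,108.6,35.7,420,55,100,percent,both,risk_mgmt
diab_care,Use of quality diabetes care,care_est,care,established,26.4,11.2,1700,57,100,percent,both,risk_mgmt
acute_care,Use of quality acute and rehabilitative care,care_est,care,established,3.7,3.0,26050,80,100,percent,none,acute_extended
postcvd_care,Use of quality CVD care post-CVD,care_est,care,established,27.4,19.2,2000,70,100,percent,post_cvd,risk_mgmt
quit_services,Use of quit counseling and NRT by smokers,care_est,care,established,51.1,5.1,619,10,20,percent,none,risk_mgmt
weight_services,Use of weight loss services by obese,care_est,care,established,75.3,7.5,650,10,24,percent,none,risk_mgmt
apnea_diag,Fraction of diagnosed sleep apnea,care_est,care,established,34.3,2.9,600,33,100,percent,none,risk_mgmt
apnea_cpap_own,Fraction with sleep apnea that own a CPAP,care_est,care,established,34.3,2.9,600,65,100,percent,none,risk_mgmt
apnea_cpap_use,Fraction that own a CPAP who use it,care_est,care,established,34.3,2.9,600,40,100,percent,none,risk_mgmt
apnea_cpap_eff,Fraction that use a CPAP who use it effectively,care_est,care,established,34.3,2.9,600,75,100,percent,none,risk_mgmt
dental_care,Regular dental care to prevent periodontal disease,care_est,care,established,129.7,55.8,300,43,100,percent,both,risk_mgmt
aspirin_m_lt65,Aspirin use by eligible non-CVD males aged under 65,care_est,care,established,39.5,11.8,14,30,100,percent,non_cvd,risk_mgmt
aspirin_f_lt65,Aspirin use by eligible non-CVD females aged under 65,care_est,care,established,18.8,7.1,14,38,100,percent,non_cvd,risk_mgmt
aspirin_m_ge65,Aspirin use by eligible non-CVD males aged 65 plus,care_est,care,established,13.1,7.9,14,60,100,percent,non_cvd,risk_mgmt
aspirin_f_ge65,Aspirin use by eligible non-CVD females aged 65 plus,care_est,care,established,15.6,8.9,14,57,100,percent,non_cvd,risk_mgmt
distress_services_non,Use of support services by distressed non-CVD,care_est,care,established,28,5.7,2080,20.6,54,percent,non_cvd,risk_mgmt
distress_services_post,Use of support services by distressed post-CVD,care_est,care,established,6.9,1.6,2080,23.4,80,percent,post_cvd,risk_mgmt
borderline_bp_care,Borderline BP care,care_emg,care,emerging,17.4,0,220,0,100,percent,both,risk_mgmt
tighter_bp_care,Tighter BP care,care_emg,care,emerging,78.7,0,88,0,100,percent,both,risk_mgmt
borderline_chol_care,Borderline cholesterol care,care_emg,care,emerging,35.8,0,378,0,100,percent,both,risk_mgmt
tighter_chol_care,Tighter cholesterol care,care_emg,care,emerging,108.6,0,126,0,100,percent,both,risk_mgmt
prediab_care,Prediabetes care,care_emg,care,emerging,73.3,0,850,0,100,percent,both,risk_mgmt
tighter_diab_care,Tighter diabetes care,care_emg,care,emerging,26.4,0,850,0,100,percent,both,risk_mgmt
tobacco_tax,Tobacco tax rate,air_est,air,established,253.4,NA,NA,34,100,index,none,none
tobacco_mktg_restrict,Tobacco marketing restriction index,air_est,air,established,253.4,NA,NA,25,100,index,none,none
workplace_smoking,Fraction of workplaces allowing smoking,air_est,air,established,253.4,NA,NA,11,0,percent,none,none
tobacco_counter_mktg,Tobacco counter-marketing index,air_emg,air,emerging,253.4,NA,NA,20,100,index,none,none
pm25,Average small particulate air pollution (ug/m3 PM2.5),air_emg,air,emerging,295.4,NA,NA,10.9,7.0,physical,none,none
pa_access,Physical activity facilities access index,life_est,lifestyle,established,295.4,NA,NA,61,100,index,none,none
pa_promotion,Physical activity promotion index,life_est,lifestyle,established,295.4,NA,NA,1,100,index,none,none
pa_schools,Physical activity in schools index,life_est,lifestyle,established,50.1,NA,NA,27,100,index,none,none
sodium_hyp,Average sodium consumption (mg/d) hypertensives,life_emg,lifestyle,emerging,78.7,NA,NA,3700,1850,physical,none,none
sodium_nonhyp,Average sodium consumption (mg/d) nonhypertensives,life_emg,lifestyle,emerging,216.8,NA,NA,4000,2000,physical,none,none
trans_fat,Trans fat fraction of calories,life_emg,lifestyle,emerging,295.4,NA,NA,1.3,0,physical,none,none
junk_tax,Junk food tax rate,life_emg,lifestyle,emerging,295.4,NA,NA,1,20,index,none,none
junk_counter_mktg,Junk food counter-marketing index,life_emg,lifestyle,emerging,295.4,NA,NA,0,100,index,none,none
fv_access,Fruit and vegetable access index,life_emg,lifestyle,emerging,295.4,NA,NA,75,100,index,none,none
fv_promotion,Fruit and vegetable promotion index,life_emg,lifestyle,emerging,295.4,NA,NA,2.5,100,index,none,none
pa_childcare,Physical activity in childcare index,life_emg,lifestyle,emerging,16.8,NA,NA,30,100,index,none,none
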