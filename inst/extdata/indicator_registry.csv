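id,name,life_stage,polarity,ceiling,units
total_population,Total population,socioeconomic,neutral,FALSE,thousands
gni_per_capita,GNI per capita,socioeconomic,higher_desirable,FALSE,USD
preprimary_enrollment,Preprimary school participation (enrollment ratio),socioeconomic,higher_desirable,FALSE,%
primary_survival,Primary school participation (survival rate to last primary grade),socioeconomic,higher_desirable,TRUE,%
secondary_enrollment,Secondary school participation (enrollment ratio),socioeconomic,higher_desirable,FALSE,%
adult_literacy,Total adult literacy rate,socioeconomic,higher_desirable,TRUE,%
life_expectancy,Life expectancy at birth,socioeconomic,higher_desirable,FALSE,years
maternal_mortality,Adjusted maternal mortality rate,gestation_birth,lower_desirable,FALSE,per 100000 live births
low_birthweight,Low birthweight prevalence,gestation_birth,lower_desirable,FALSE,%
neonatal_mortality,Neonatal mortality rate,gestation_birth,lower_desirable,FALSE,per 1000 live births
infant_mortality,Infant mortality rate (<12 months),infancy_under5,lower_desirable,FALSE,per 1000 live births
exclusive_breastfeeding,Exclusive breastfeeding <6 months,infancy_under5,higher_desirable,FALSE,%
solid_food_introduction,Introduction of solid/semi-solid/soft food 6-8 months,infancy_under5,higher_desirable,FALSE,%
iodized_salt,Adequate iodized salt consumption,infancy_under5,higher_desirable,FALSE,%
vitamin_a_supplementation,Vitamin A supplementation full coverage,infancy_under5,higher_desirable,TRUE,%
underweight_u5,Underweight prevalence <5 years,infancy_under5,lower_desirable,FALSE,%
stunting_u5,Stunting prevalence <5 years,infancy_under5,lower_desirable,FALSE,%
wasting_u5,Wasting prevalence <5 years,infancy_under5,lower_desirable,FALSE,%
overweight_u5,Overweight prevalence <5 years,infancy_under5,lower_desirable,FALSE,%
under5_mortality,Mortality rate <5 years,infancy_under5,lower_desirable,FALSE,per 1000 live births
diarrhea_deaths_wash_u5,Diarrhea deaths from inadequate WASH <5 years,wash,lower_desirable,FALSE,per 100000
basic_water_urban,Population using at least basic drinking-water services (urban),wash,higher_desirable,FALSE,%
basic_water_rural,Population using at least basic drinking-water services (rural),wash,higher_desirable,FALSE,%
basic_water_national,Population using at least basic drinking-water services (national),wash,higher_desirable,FALSE,%
basic_sanitation_urban,Population using at least basic sanitation services (urban),wash,higher_desirable,FALSE,%
basic_sanitation_rural,Population using at least basic sanitation services (rural),wash,higher_desirable,FALSE,%
basic_sanitation_national,Population using at least basic sanitation services (national),wash,higher_desirable,FALSE,%
insufficient_activity_men,Prevalence of insufficient physical activity (men),adult_lifestyle,lower_desirable,FALSE,%
insufficient_activity_women,Prevalence of insufficient physical activity (women),adult_lifestyle,lower_desirable,FALSE,%
alcohol_consumption,Alcohol consumption per capita,adult_lifestyle,lower_desirable,FALSE,litres pure alcohol
alcohol_disorders_men,Alcohol-use disorders 12-month prevalence (men),adult_lifestyle,lower_desirable,FALSE,%
alcohol_disorders_women,Alcohol-use disorders 12-month prevalence (women),adult_lifestyle,lower_desirable,FALSE,%
tobacco_smoking_men,Current tobacco smoking (men),adult_lifestyle,lower_desirable,FALSE,%
tobacco_smoking_women,Current tobacco smoking (women),adult_lifestyle,lower_desirable,FALSE,%
mean_bmi_men,Mean body mass index (men),adult_biomarker,lower_desirable,FALSE,kg/m2
mean_bmi_women,Mean body mass index (women),adult_biomarker,lower_desirable,FALSE,kg/m2
overweight_adult_men,Overweight BMI>=25 (men),adult_biomarker,lower_desirable,FALSE,%
overweight_adult_women,Overweight BMI>=25 (women),adult_biomarker,lower_desirable,FALSE,%
obesity_men,Obesity BMI>=30 (men),adult_biomarker,lower_desirable,FALSE,%
obesity_women,Obesity BMI>=30 (women),adult_biomarker,lower_desirable,FALSE,%
raised_bp_men,Raised blood pressure SBP>=140/DBP>=90 (men),adult_biomarker,lower_desirable,FALSE,%
raised_bp_women,Raised blood pressure SBP>=140/DBP>=90 (women),adult_biomarker,lower_desirable,FALSE,%
raised_glucose_men,Raised fasting blood glucose (men),adult_biomarker,lower_desirable,FALSE,%
raised_glucose_women,Raised fasting blood glucose (women),adult_biomarker,lower_desirable,FALSE,%
diabetes_mortality_men,Diabetes mortality (men),ncd_mortality,lower_desirable,FALSE,per 100000
diabetes_mortality_women,Diabetes mortality (women),ncd_mortality,lower_desirable,FALSE,per 100000
cvd_mortality_men,Cardiovascular disease mortality (men),ncd_mortality,lower_desirable,FALSE,per 100000
cvd_mortality_women,Cardiovascular disease mortality (women),ncd_mortality,lower_desirable,FALSE,per 100000
respiratory_mortality_men,Chronic respiratory disease mortality (men),ncd_mortality,lower_desirable,FALSE,per 100000
respiratory_mortality_women,Chronic respiratory disease mortality (women),ncd_mortality,lower_desirable,FALSE,per 100000
cancer_mortality_men,Cancer mortality (men),ncd_mortality,lower_desirable,FALSE,per 100000
cancer_mortality_women,Cancer mortality (women),ncd_mortality,lower_desirable,FALSE,per 100000
other_ncd_mortality,Other NCD mortality,ncd_mortality,lower_desirable,FALSE,per 100000
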