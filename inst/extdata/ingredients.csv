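intervention_id,item,category,quantity_per_case,unit_price_usd,delivery_point
contraceptive_info,information leaflet set,medical_supply,1,0.15,any
contraceptive_info,counseling visit,service_delivery,1,,any
contraceptive_provision,oral contraceptive cycle,drug,13,0.45,any
contraceptive_provision,counseling and provision visits,service_delivery,2,,any
condom_distribution,condoms (annual supply),medical_supply,120,0.03,any
condom_distribution,distribution contact,service_delivery,1,,any
anc,iron-folate supplementation (pregnancy course),drug,1,1.80,any
anc,syphilis screening test,lab_test,1,0.55,any
anc,urine test strips,lab_test,4,0.10,any
anc,antenatal visits,service_delivery,4,,any
childbirth_care,delivery kit,medical_supply,1,3.50,any
childbirth_care,oxytocin 10 IU,drug,1,0.40,any
childbirth_care,facility days for delivery,service_delivery,2,,any
postnatal_care,vitamin A supplementation,drug,1,0.25,any
postnatal_care,postnatal visits,service_delivery,2,,any
pmtct,HIV rapid test,lab_test,2,0.80,any
pmtct,antiretroviral prophylaxis course,drug,1,12.00,any
pmtct,PMTCT visits,service_delivery,3,,any
htc,HIV rapid test,lab_test,1,0.80,any
htc,confirmatory test,lab_test,0.1,1.50,any
htc,counseling and testing visit,service_delivery,1,,any
sti_syphilis,benzathine penicillin 2.4 MU,drug,1,0.65,any
sti_syphilis,RPR test,lab_test,1,0.55,any
sti_syphilis,treatment visit,service_delivery,1,,any
sti_gonorrhoea,cefixime 400 mg,drug,1,0.50,any
sti_gonorrhoea,treatment visit,service_delivery,1,,any
sti_chlamydia,azithromycin 1 g,drug,1,0.70,any
sti_chlamydia,treatment visit,service_delivery,1,,any
sti_pid,ceftriaxone plus doxycycline course,drug,1,2.10,any
sti_pid,treatment visits,service_delivery,2,,any
abortion_care,manual vacuum aspiration kit (amortized per case),medical_supply,1,4.00,any
abortion_care,misoprostol 200 mcg,drug,3,0.30,any
abortion_care,procedure visit,service_delivery,1,,any
post_abortion_care,antibiotic prophylaxis course,drug,1,0.90,any
post_abortion_care,follow-up visits,service_delivery,2,,any
needle_syringe_exchange,needle-syringe sets (annual supply),medical_supply,200,0.08,any
needle_syringe_exchange,outreach contacts,service_delivery,12,,any
ost,methadone (annual maintenance),drug,365,0.35,any
ost,dispensing and review visits,service_delivery,24,,any
ipv_injury_care,wound care supplies,medical_supply,1,2.50,any
ipv_injury_care,emergency contraception,drug,1,0.60,any
ipv_injury_care,care visits,service_delivery,2,,any
hiv_oi_care,cotrimoxazole prophylaxis (annual),drug,365,0.02,any
hiv_oi_care,CD4 count test,lab_test,2,8.00,any
hiv_oi_care,clinical review visits,service_delivery,4,,any
art,first-line ARV regimen (annual),drug,1,130.00,any
art,viral load / CD4 monitoring,lab_test,2,8.00,any
art,ART visits,service_delivery,4,,any
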