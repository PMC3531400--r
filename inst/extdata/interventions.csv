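intervention_id,number,name,intervention_group,package,need_basis,need_lo_pct,need_hi_pct,cov_lo_pct,cov_hi_pct,target_coverage_pct,share_hospital_pct,share_primary_pct,share_community_pct,sex_filter,requires_abortion_legal,requires_harm_reduction,costed_in
contraceptive_info,1a,Information on contraception,contraceptive_services,preventive_essential,all_adolescents,19,99,2,30,95,0,90,10,both,FALSE,FALSE,main_model
contraceptive_provision,1b,Contraceptive counseling and provision,contraceptive_services,preventive_essential,sexually_active,0,81,0,75,95,0,95,5,both,FALSE,FALSE,main_model
condom_distribution,1c,Condom distribution,contraceptive_services,preventive_essential,sexually_active,0,81,0,69,95,0,50,50,both,FALSE,FALSE,main_model
anc,2a,Basic antenatal care,maternity_care,preventive_essential,female_adolescents,3,29,0,98.8,95,90,5,5,female,FALSE,FALSE,maternity_model
childbirth_care,2b,Care during childbirth,maternity_care,preventive_essential,female_adolescents,3,29,98.8,98.8,95,25,75,0,female,FALSE,FALSE,maternity_model
postnatal_care,2c,Postpartum and postnatal care,maternity_care,preventive_essential,female_adolescents,3,29,98.8,98.8,95,0,60,40,female,FALSE,FALSE,maternity_model
pmtct,2d,Prevention of mother-to-child transmission of HIV,maternity_care,preventive_essential,female_adolescents,0,1,98.8,98.8,95,20,80,0,female,FALSE,FALSE,maternity_model
htc,3,HIV testing and counseling,htc,preventive_essential,sexually_active,0,81,0,35,95,80,20,0,both,FALSE,FALSE,main_model
sti_syphilis,4a,Management of syphilis,sti_management,curative_essential,condition_share,0,5,0,81,95,80,20,0,both,FALSE,FALSE,main_model
sti_gonorrhoea,4b,Management of gonorrhoea,sti_management,curative_essential,condition_share,0,8,0,81,95,80,20,0,both,FALSE,FALSE,main_model
sti_chlamydia,4c,Management of chlamydia,sti_management,curative_essential,condition_share,1,5,0,81,95,80,20,0,both,FALSE,FALSE,main_model
sti_pid,4d,Management of pelvic inflammatory disease,sti_management,curative_essential,female_adolescents,2,4,0,81,95,80,20,0,female,FALSE,FALSE,main_model
abortion_care,5a,Safe abortion care,safe_abortion,curative_essential,female_adolescents,1,4,0,95,95,80,20,0,female,TRUE,FALSE,main_model
post_abortion_care,5b,Post-abortion care,safe_abortion,curative_essential,female_adolescents,1,4,0,75,95,20,80,0,female,TRUE,FALSE,main_model
needle_syringe_exchange,6a,Needle and syringe exchange,harm_reduction,preventive_expanded,condition_share,0,1,0,81,95,0,30,70,both,FALSE,TRUE,main_model
ost,6b,Opioid substitution therapy,harm_reduction,preventive_expanded,condition_share,0,0.5,0,67,50,0,100,0,both,FALSE,TRUE,main_model
ipv_injury_care,7,Care of injuries due to intimate partner violence,ipv_injury_care,curative_expanded,female_adolescents,0,12,0,1,95,70,20,10,female,FALSE,FALSE,main_model
hiv_oi_care,8a,"HIV care, support and treatment of opportunistic infections",hiv_care_treatment,curative_expanded,hiv_positive,0,3,0,58,95,85,15,0,both,FALSE,FALSE,main_model
art,8b,Antiretroviral therapy provision,hiv_care_treatment,curative_expanded,hiv_positive,0,1,17,83,95,85,15,0,both,FALSE,FALSE,main_model
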