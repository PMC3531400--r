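activity_id,category,level,item,quantity,unit_price_usd,scaling_driver
pm_national,management,national,coordination meetings (per diems and travel),60,200,per_country_year
pm_national,management,national,policy assessment and revision consultancy,1,30000,per_country_year
pm_national,management,national,national AFHS standards production and distribution,1,15000,per_country_year
pm_district,management,district,district coordination meetings (per diems and travel),12,150,per_district
supervision_district,supervision,district,supervisory visits to facilities (per diems and travel),24,80,per_district
supervision_facility,supervision,facility,supervision of community health workers,8,50,per_facility
training_facility,training,facility,health worker training sessions (per diems travel materials),2,450,per_facility
training_community,training,community,community worker orientation sessions,2,150,per_facility
training_national,training,national,pre-service curriculum adaptation,1,25000,per_country_year
iec_national,IEC,national,radio adverts and billboards per 1000 adolescents,6,40,per_population
iec_facility,IEC,community,posters and leaflets per 1000 adolescents,1000,0.25,per_population
iec_facility,IEC,community,sensitization sessions per 1000 adolescents,10,30,per_population
infrastructure_facility,infrastructure_equipment,facility,screen walls and privacy partitions,1,150,per_facility
infrastructure_facility,infrastructure_equipment,facility,secure cabinets,1,80,per_facility
infrastructure_facility,infrastructure_equipment,facility,paint and decoration supplies,1,40,per_facility
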