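number,dimension,text
1,equitable,Policies and procedures do not restrict the provision of health services on any terms
2,equitable,Health-care providers treat all adolescent clients with equal care and respect regardless of status
3,equitable,Support staff treat all adolescent clients with equal care and respect regardless of status
4,accessible,Policies and procedures ensure that health services are free or affordable to adolescents
5,accessible,The point of service delivery has convenient hours of operation
6,accessible,Adolescents are well informed about the range of available reproductive health services and how to obtain them
7,accessible,Community members understand the benefits adolescents gain from the health services they need and support their provision
8,accessible,Selected community members outreach workers and adolescents themselves provide some services and commodities in the community
9,acceptable,Policies and procedures guarantee client confidentiality
10,acceptable,The point of service delivery ensures privacy
11,acceptable,Health-care providers are non-judgmental considerate and easy to relate to
12,acceptable,Consultations occur with short waiting times with or without appointment and with swift referral where necessary
13,acceptable,The point of service delivery has an appealing and clean environment
14,acceptable,The point of service delivery provides information and education through a variety of channels
15,acceptable,Adolescents are actively involved in designing assessing and providing health services
16,appropriate,The required package of care is provided at the point of service delivery or through referral linkages to fulfil the needs of all adolescents
17,effective,Health-care providers have the required competencies to work with adolescents and provide the required services
18,effective,Health-care providers use evidence-based protocols and guidelines to provide health services
19,effective,Health-care providers are able to dedicate sufficient time to work effectively with adolescent clients
20,effective,The point of service delivery has the equipment supplies and basic services necessary to deliver the required care
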