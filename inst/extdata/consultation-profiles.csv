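professional_category,n
state_service,39
local_community_housing_professional,39
decent_housing_association,22
social_or_medicosocial_worker,14
indoor_environment_consultant,11
real_estate_professional,8
citizen,5
academic_research,4
other,4
elected_official,3
social_landlord,2
private_landlord,0
health_agency,0
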