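dimension,level,n
setting,urban,20
setting,rural,8
area,metropolitan,19
area,overseas,9
housing_type,collective,19
housing_type,individual,9
tenure,private_rental,13
tenure,social_housing,9
tenure,owner_occupant,6
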