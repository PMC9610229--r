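drug,excipient,polymer_grade,length_mm,wall_thickness_um,outer_diameter_mm,drug_excipient_ratio,drug_loading_mg
BIC,Castor Oil,PC-17,40,200,2.5,2:1,116
EFdA,Castor Oil,PC-17,10,200,2.5,1:1,22
ENG,Ethyl Oleate,Sigma,10,70,2.5,1:4,7.9
FTC,Castor Oil,PC-17,40,200,2.5,1:1,82
LNG,Ethyl Oleate,Sigma,10,70,2.5,1:4,6.9
TAF_salt,PEG_600,Sigma,40,100,2.5,2:1,124
3TC,Castor Oil,PC-17,40,200,2.5,2:1,117
ABC,PEG_400,PC-17,10,200,2.5,2:1,25
DTG_salt,Oleic Acid,PC-31,10,150,2.5,2:1,82
RAL_salt,Glycerol,PC-31,40,150,2.5,2:1,97
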