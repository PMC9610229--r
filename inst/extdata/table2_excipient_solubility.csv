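excipient,drug,source,cse_mg_ml,cse_sd_mg_ml
Castor Oil,BIC,,4.35,1.58
Castor Oil,EFdA,Wuxi,1.81,0.10
Castor Oil,EFdA,Pharmaron,2.50,0.18
Castor Oil,ENG,,16.20,0.76
Castor Oil,FTC,,0.906,0.14
Castor Oil,LNG,,1.24,0.21
Castor Oil,TAF_base,,16.75,0.23
Castor Oil,TAF_salt,,12.4,0.01
Cottonseed Oil,BIC,,2.19,1.13
Cottonseed Oil,EFdA,Wuxi,0.04,0.01
Cottonseed Oil,EFdA,Pharmaron,0.057,0.002
Cottonseed Oil,ENG,,3.98,0.07
Cottonseed Oil,FTC,,0.011,0.002
Cottonseed Oil,LNG,,0.51,0.07
Cottonseed Oil,TAF_base,,0.19,0.18
Cottonseed Oil,TAF_salt,,0.168,0.004
Ethyl Oleate,BIC,,0.62,0.24
Ethyl Oleate,EFdA,Wuxi,0.04,0.01
Ethyl Oleate,EFdA,Pharmaron,0.05,0.001
Ethyl Oleate,ENG,,5.60,0.05
Ethyl Oleate,FTC,,0.015,0.002
Ethyl Oleate,LNG,,0.59,0.03
Ethyl Oleate,TAF_base,,0.21,0.15
Ethyl Oleate,TAF_salt,,0.11,0.01
Glycerol,BIC,,3.81,1.21
Glycerol,EFdA,Wuxi,21.9,0.22
Glycerol,EFdA,Pharmaron,11.5,0.14
Glycerol,ENG,,2.02,1.20
Glycerol,FTC,,36.9,1.69
Glycerol,LNG,,0.55,0.23
Glycerol,TAF_base,,29.19,2.73
Glycerol,TAF_salt,,41.8,0.55
Oleic Acid,BIC,,15.9,0.29
Oleic Acid,EFdA,Wuxi,0.71,0.23
Oleic Acid,EFdA,Pharmaron,0.054,0.001
Oleic Acid,ENG,,4.73,0.37
Oleic Acid,FTC,,0.5,0.01
Oleic Acid,LNG,,0.50,0.14
Oleic Acid,TAF_base,,52.96,2.08
Oleic Acid,TAF_salt,,59.9,0.71
PEG_300,BIC,,24.8,1.42
PEG_300,EFdA,Wuxi,69.89,0.86
PEG_300,EFdA,Pharmaron,11.4,0.16
PEG_300,ENG,,32.95,0.93
PEG_300,FTC,,37.0,3.71
PEG_300,LNG,,3.68,0.33
PEG_300,TAF_base,,66.93,3.79
PEG_300,TAF_salt,,65.2,0.36
PEG_400,BIC,,24.8,5.83
PEG_400,EFdA,Wuxi,68.37,3.52
PEG_400,EFdA,Pharmaron,14.2,0.13
PEG_400,ENG,,32.82,1.13
PEG_400,FTC,,37.2,1.76
PEG_400,LNG,,3.83,0.23
PEG_400,TAF_base,,67.05,2.96
PEG_400,TAF_salt,,39.9,0.18
PEG_600,BIC,,25.4,1.83
PEG_600,EFdA,Wuxi,62.87,0.52
PEG_600,EFdA,Pharmaron,14.2,0.13
PEG_600,ENG,,31.10,1.26
PEG_600,FTC,,39.0,0.82
PEG_600,LNG,,3.81,0.07
PEG_600,TAF_base,,59.60,3.22
PEG_600,TAF_salt,,57.6,0.44
PEG_40 Castor Oil,BIC,,22.1,3.00
PEG_40 Castor Oil,EFdA,Wuxi,37.54,0.60
PEG_40 Castor Oil,EFdA,Pharmaron,22.2,0.21
PEG_40 Castor Oil,ENG,,28.02,1.71
PEG_40 Castor Oil,FTC,,21.2,0.21
PEG_40 Castor Oil,LNG,,4.13,0.46
PEG_40 Castor Oil,TAF_base,,18.37,1.46
PEG_40 Castor Oil,TAF_salt,,28.4,0.22
Polysorbate 80,BIC,,24.1,0.72
Polysorbate 80,EFdA,Wuxi,35.02,1.00
Polysorbate 80,EFdA,Pharmaron,16.9,0.047
Polysorbate 80,ENG,,25.44,1.55
Polysorbate 80,FTC,,14.8,0.17
Polysorbate 80,LNG,,3.49,0.54
Polysorbate 80,TAF_base,,19.06,3.12
Polysorbate 80,TAF_salt,,28.5,0.85
Propylene Glycol,BIC,,24.2,4.09
Propylene Glycol,EFdA,Wuxi,41.45,1.22
Propylene Glycol,EFdA,Pharmaron,16.9,0.05
Propylene Glycol,ENG,,18.66,1.28
Propylene Glycol,FTC,,38.6,0.49
Propylene Glycol,LNG,,3.49,0.54
Propylene Glycol,TAF_base,,63.59,4.15
Propylene Glycol,TAF_salt,,75.8,0.86
Sesame Oil,BIC,,1.75,1.02
Sesame Oil,EFdA,Wuxi,0.03,0.01
Sesame Oil,EFdA,Pharmaron,0.22,0.01
Sesame Oil,ENG,,3.74,0.06
Sesame Oil,FTC,,0.020,0.006
Sesame Oil,LNG,,0.54,0.04
Sesame Oil,TAF_base,,0.06,0.004
Sesame Oil,TAF_salt,,0.34,0.11
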