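class_code,class_name,eps_luemax
ENF,Evergreen Needleleaf Forests,0.962
EBF,Evergreen Broadleaf Forests,1.268
DNF,Deciduous Needleleaf Forests,1.086
DBF,Deciduous Broadleaf Forests,1.165
MF,Mixed Forests,1.051
CSH,Closed Shrublands,1.281
OSH,Open Shrublands,0.841
WSA,Woody Savannas,1.239
SAV,Savannas,1.206
GRA,Grasslands,0.860
CRO,Croplands,1.044
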