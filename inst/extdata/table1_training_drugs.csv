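drug,supplier,logp,mw_da,csp_mg_ml,pka
LNG,Selleck,3.8,312.5,0.0071,17.9
ENG,AdooQ,3.3,324.6,0.0093,10.4
TAF_salt,Gilead,1.49,534.5,11.59,11.36
TAF_base,Gilead,1.8,476.5,4.98,3.96
EFdA,Wuxi/Pharm,-1.19,293.2,1.05,13.32
BIC,AstaTech,1.71,449.4,0.17,9.81
FTC,BOC Sciences,-0.43,247.2,165.6,2.65
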