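drug,supplier,logp,mw_da,csp_mg_ml,pka
3TC,Ambeed,-1.4,229.3,78.1,14.29
ABC,TCI America,1.335,286.3,2.55,4.8
DTG_salt,BOC Sciences,2.2,441.4,0.08,8.2
RAL_salt,BOC Sciences,1.59,482.5,64.99,7.02
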