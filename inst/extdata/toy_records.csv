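record_id,smiles,label,endpoint,source,guideline_compliant
r01,CC(=O)[O-].[Na+],1,mn_in_vitro,salt_example,TRUE
r02,CCN.Cl,0,mn_in_vitro,salt_example,TRUE
r03,CCO.OCC,1,mn_in_vitro,mixture_example,TRUE
r04,N[Pt](N)(Cl)Cl,1,mn_in_vitro,organometallic_example,TRUE
r05,c1ccccc1,1,mn_in_vitro,conflict_pair,FALSE
r06,C1=CC=CC=C1,0,mn_in_vitro,conflict_pair,TRUE
r07,CCO,1,mn_in_vitro,identical_pair,TRUE
r08,OCC,1,mn_in_vitro,identical_pair,TRUE
r09,Cc1ccccc1,1,mn_in_vitro,plain,TRUE
r10,CCOC(N)=O,1,mn_in_vitro,plain,TRUE
r11,Oc1ccccc1,0,mn_in_vitro,plain,TRUE
r12,CC(C)=O,0,mn_in_vitro,plain,TRUE
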