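product_id,ingredients,route,dosage_form,strength,rx_status,drug_type,common_use,is_supply,is_mdi
ESTR,estradiol,transdermal,patch,0.025 mg/24 h,prescription,standard,regular,false,false
METO,metoprolol succinate,oral,tablet,50 mg,prescription,standard,regular,false,false
EZSI,ezetimibe|simvastatin,oral,tablet,10/10 mg,prescription,standard,regular,false,false
NITR,nitroglycerin,sublingual,tablet,0.4 mg,prescription,standard,as_needed,false,false
LISI,lisinopril,oral,tablet,10 mg,prescription,standard,regular,false,false
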