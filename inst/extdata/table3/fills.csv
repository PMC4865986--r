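patient_id,product_id,fill_date,days_supply,quantity
hp01,ESTR,2008-04-19,28,4
hp01,EZSI,2008-04-19,30,30
hp01,METO,2008-04-19,30,30
hp01,NITR,2008-04-19,9,25
hp01,ESTR,2008-05-20,28,4
hp01,EZSI,2008-05-20,30,30
hp01,METO,2008-05-20,30,30
hp01,ESTR,2008-06-18,28,4
hp01,EZSI,2008-06-18,30,30
hp01,METO,2008-06-18,30,30
hp01,LISI,2008-07-03,30,30
hp01,ESTR,2008-07-19,28,4
hp01,EZSI,2008-07-19,30,30
hp01,METO,2008-07-19,30,30
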