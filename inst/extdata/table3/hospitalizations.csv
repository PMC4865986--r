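patient_id,admit_date,discharge_date
hp01,2008-07-01,2008-07-03
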