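class,pt
off_label,OFF LABEL USE
product_issue,PRODUCT DOSE OMISSION ISSUE
product_issue,PRODUCT QUALITY ISSUE
medication_error,MEDICATION ERROR
medication_error,ACCIDENTAL OVERDOSE
indication,EPILEPSY
indication,SEIZURE
indication,STATUS EPILEPTICUS
indication,PARTIAL SEIZURES
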