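pt,soc_code
BRADYCARDIA,10007541
CARDIAC ARREST,10007541
ATRIOVENTRICULAR BLOCK,10007541
ATRIAL FIBRILLATION,10007541
ATRIOVENTRICULAR BLOCK COMPLETE,10007541
CARDIO-RESPIRATORY ARREST,10007541
ARRHYTHMIA,10007541
SINUS BRADYCARDIA,10007541
ATRIOVENTRICULAR BLOCK SECOND DEGREE,10007541
VENTRICULAR TACHYCARDIA,10007541
SINUS NODE DYSFUNCTION,10007541
VENTRICULAR FIBRILLATION,10007541
SINUS ARREST,10007541
ATRIOVENTRICULAR BLOCK FIRST DEGREE,10007541
ATRIAL FLUTTER,10007541
SINOATRIAL BLOCK,10007541
CONDUCTION DISORDER,10007541
PALPITATIONS,10007541
TACHYCARDIA,10007541
CARDIAC FAILURE,10007541
MYOCARDIAL INFARCTION,10007541
CARDIAC DISORDER,10007541
NAUSEA,10017947
VOMITING,10017947
DIARRHOEA,10017947
HEADACHE,10029205
DIZZINESS,10029205
SOMNOLENCE,10029205
SEIZURE,10029205
EPILEPSY,10029205
STATUS EPILEPTICUS,10029205
PARTIAL SEIZURES,10029205
FATIGUE,10018065
DRUG INEFFECTIVE,10018065
RASH,10040785
PRURITUS,10040785
DYSPNOEA,10038738
INSOMNIA,10037175
ANXIETY,10037175
FALL,10022117
OFF LABEL USE,10022117
PRODUCT DOSE OMISSION ISSUE,10022117
PRODUCT QUALITY ISSUE,10022117
MEDICATION ERROR,10022117
ACCIDENTAL OVERDOSE,10022117
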