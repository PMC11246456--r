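pt,soc_code,background_rate
BRADYCARDIA,10007541,30
CARDIAC ARREST,10007541,40
ATRIOVENTRICULAR BLOCK,10007541,8
ATRIAL FIBRILLATION,10007541,60
ATRIOVENTRICULAR BLOCK COMPLETE,10007541,6
CARDIO-RESPIRATORY ARREST,10007541,25
ARRHYTHMIA,10007541,30
SINUS BRADYCARDIA,10007541,10
ATRIOVENTRICULAR BLOCK SECOND DEGREE,10007541,3
VENTRICULAR TACHYCARDIA,10007541,15
SINUS NODE DYSFUNCTION,10007541,4
VENTRICULAR FIBRILLATION,10007541,10
SINUS ARREST,10007541,3
ATRIOVENTRICULAR BLOCK FIRST DEGREE,10007541,4
ATRIAL FLUTTER,10007541,12
SINOATRIAL BLOCK,10007541,2
CONDUCTION DISORDER,10007541,4
PALPITATIONS,10007541,80
TACHYCARDIA,10007541,70
CARDIAC FAILURE,10007541,50
MYOCARDIAL INFARCTION,10007541,60
CARDIAC DISORDER,10007541,20
NAUSEA,10017947,400
VOMITING,10017947,300
DIARRHOEA,10017947,350
HEADACHE,10029205,350
DIZZINESS,10029205,450
SOMNOLENCE,10029205,200
SEIZURE,10029205,250
EPILEPSY,10029205,80
STATUS EPILEPTICUS,10029205,30
PARTIAL SEIZURES,10029205,20
FATIGUE,10018065,400
DRUG INEFFECTIVE,10018065,300
RASH,10040785,300
PRURITUS,10040785,200
DYSPNOEA,10038738,250
INSOMNIA,10037175,150
ANXIETY,10037175,150
FALL,10022117,200
OFF LABEL USE,10022117,120
PRODUCT DOSE OMISSION ISSUE,10022117,60
PRODUCT QUALITY ISSUE,10022117,30
MEDICATION ERROR,10022117,50
ACCIDENTAL OVERDOSE,10022117,30
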