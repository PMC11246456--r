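BRADYCARDIA
CARDIAC ARREST
ATRIOVENTRICULAR BLOCK
ATRIAL FIBRILLATION
ATRIOVENTRICULAR BLOCK COMPLETE
CARDIO-RESPIRATORY ARREST
ARRHYTHMIA
SINUS BRADYCARDIA
ATRIOVENTRICULAR BLOCK SECOND DEGREE
VENTRICULAR TACHYCARDIA
ATRIOVENTRICULAR BLOCK FIRST DEGREE
ATRIAL FLUTTER
CONDUCTION DISORDER
PALPITATIONS
TACHYCARDIA
DIZZINESS
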