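BRADYCARDIA
CARDIAC ARREST
ATRIOVENTRICULAR BLOCK
ATRIAL FIBRILLATION
ATRIOVENTRICULAR BLOCK COMPLETE
ARRHYTHMIA
SINUS BRADYCARDIA
ATRIOVENTRICULAR BLOCK SECOND DEGREE
VENTRICULAR TACHYCARDIA
SINUS NODE DYSFUNCTION
VENTRICULAR FIBRILLATION
SINUS ARREST
ATRIOVENTRICULAR BLOCK FIRST DEGREE
ATRIAL FLUTTER
SINOATRIAL BLOCK
CONDUCTION DISORDER
MYOCARDIAL INFARCTION
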