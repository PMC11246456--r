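pt,n,ror025,n_deaths,importance,evidence,published_score,published_level
BRADYCARDIA,135,4.94,4,IME,++,6,moderate
CARDIAC ARREST,80,1.92,23,IME,++,6,moderate
ATRIOVENTRICULAR BLOCK,67,16.80,8,IME,++,7,moderate
ATRIAL FIBRILLATION,67,1.21,2,IME,+,4,weak
ATRIOVENTRICULAR BLOCK COMPLETE,58,17.23,5,IME,++,7,moderate
CARDIO-RESPIRATORY ARREST,39,1.68,27,NA,+,4,weak
ARRHYTHMIA,34,1.22,3,IME,++,4,weak
SINUS BRADYCARDIA,29,5.07,0,IME,++,6,moderate
ATRIOVENTRICULAR BLOCK SECOND DEGREE,27,15.19,1,IME,++,5,moderate
VENTRICULAR TACHYCARDIA,26,2.92,2,IME,++,5,moderate
SINUS NODE DYSFUNCTION,19,10.10,1,IME,++,6,moderate
VENTRICULAR FIBRILLATION,15,2.16,4,DME,++,7,moderate
SINUS ARREST,14,14.13,0,IME,++,6,moderate
ATRIOVENTRICULAR BLOCK FIRST DEGREE,14,4.52,3,IME,++,5,moderate
ATRIAL FLUTTER,14,2.35,0,IME,++,5,moderate
SINOATRIAL BLOCK,5,8.57,0,IME,++,5,moderate
CONDUCTION DISORDER,5,3.12,0,IME,++,4,weak
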