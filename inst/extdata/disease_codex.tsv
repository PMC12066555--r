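term	alias_of
hypertension
heart failure
congestive heart failure
myocardial infarction
acute myocardial infarction
angina pectoris
exertional angina pectoris
atrial fibrillation
sinus bradycardia
bradycardia
glaucoma
hereditary long QT
diabetes
hypotension
atrioventricular block
high blood pressure	hypertension
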