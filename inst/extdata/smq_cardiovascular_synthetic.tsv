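smq_id	smq_name	pt_term
venous_thrombotic_diseases	Venous thrombotic diseases	Pulmonary embolism
venous_thrombotic_diseases	Venous thrombotic diseases	Deep vein thrombosis
venous_thrombotic_diseases	Venous thrombotic diseases	Venous thrombosis
venous_thrombotic_diseases	Venous thrombotic diseases	Thrombosis
venous_thrombotic_diseases	Venous thrombotic diseases	Embolism
venous_thrombotic_diseases	Venous thrombotic diseases	Jugular vein thrombosis
abnormal_blood_pressure	Abnormal blood pressure	Hypotension
abnormal_blood_pressure	Abnormal blood pressure	Hypertension
abnormal_blood_pressure	Abnormal blood pressure	Blood pressure increased
abnormal_blood_pressure	Abnormal blood pressure	Blood pressure decreased
abnormal_blood_pressure	Abnormal blood pressure	Hypertensive crisis
arrhythmia	Arrhythmia	Tachycardia
arrhythmia	Arrhythmia	Atrial fibrillation
arrhythmia	Arrhythmia	Ventricular tachycardia
arrhythmia	Arrhythmia	Bradycardia
arrhythmia	Arrhythmia	Arrhythmia
arrhythmia	Arrhythmia	Palpitations
pericardial_effusion	Pericardial effusion	Pericardial effusion
pericardial_effusion	Pericardial effusion	Cardiac tamponade
pericardial_effusion	Pericardial effusion	Pericarditis
cardiac_failure	Cardiac failure	Cardiac failure
cardiac_failure	Cardiac failure	Cardiac failure congestive
cardiac_failure	Cardiac failure	Cardiac failure acute
cardiac_failure	Cardiac failure	Ejection fraction decreased
stroke	Stroke	Cerebrovascular accident
stroke	Stroke	Ischaemic stroke
stroke	Stroke	Haemorrhagic stroke
stroke	Stroke	Transient ischaemic attack
stroke	Stroke	Cerebral infarction
sudden_death	Sudden death	Sudden death
sudden_death	Sudden death	Sudden cardiac death
sudden_death	Sudden death	Cardiac arrest
sudden_death	Sudden death	Cardio-respiratory arrest
coronary_artery_disease	Coronary artery disease	Myocardial infarction
coronary_artery_disease	Coronary artery disease	Acute myocardial infarction
coronary_artery_disease	Coronary artery disease	Acute coronary syndrome
coronary_artery_disease	Coronary artery disease	Angina pectoris
coronary_artery_disease	Coronary artery disease	Coronary artery disease
myocardial_injury	Myocardial injury	Myocardial injury
myocardial_injury	Myocardial injury	Troponin increased
myocardial_injury	Myocardial injury	Myocarditis
peripheral_vascular_disease	Peripheral vascular disease	Peripheral arterial occlusive disease
peripheral_vascular_disease	Peripheral vascular disease	Arterial thrombosis limb
peripheral_vascular_disease	Peripheral vascular disease	Peripheral ischaemia
peripheral_vascular_disease	Peripheral vascular disease	Intermittent claudication
cardiomyopathy_other	Cardiomyopathy and other cardiac disorders	Cardiomyopathy
cardiomyopathy_other	Cardiomyopathy and other cardiac disorders	Dilated cardiomyopathy
cardiomyopathy_other	Cardiomyopathy and other cardiac disorders	Stress cardiomyopathy
cardiomyopathy_other	Cardiomyopathy and other cardiac disorders	Left ventricular dysfunction
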