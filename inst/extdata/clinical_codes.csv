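code,description,category
E200.,Anxiety state (synthetic fixture),anxiety_diagnosis
E2000,Anxiety state unspecified (synthetic fixture),anxiety_diagnosis
Eu41.,Other anxiety disorders (synthetic fixture),anxiety_diagnosis
E202.,Generalized anxiety disorder (synthetic fixture),anxiety_diagnosis
1B13.,Anxiousness (synthetic fixture),anxiety_symptom
1B1V.,C/O - feeling anxious (synthetic fixture),anxiety_symptom
R2y10,Nervousness (synthetic fixture),anxiety_symptom
173f.,Stress-related symptom (synthetic fixture),anxiety_symptom
Eu412,Mixed anxiety and depressive disorder (synthetic fixture),mixed_anxiety_depression
E2003,Anxiety with depression (synthetic fixture),mixed_anxiety_depression
Eu410,Panic disorder (synthetic fixture),panic
E2001,Panic attack (synthetic fixture),panic
E2B..,Depressive disorder NEC (synthetic fixture),depression_diagnosis
Eu32.,Depressive episode (synthetic fixture),depression_diagnosis
E204.,Neurotic depression reactive type (synthetic fixture),depression_diagnosis
E2B1.,Recurrent major depressive episode (synthetic fixture),depression_diagnosis
1BT..,Depressed mood (synthetic fixture),depression_symptom
1B17.,Low mood (synthetic fixture),depression_symptom
R007z,Tearfulness (synthetic fixture),depression_symptom
1BQ..,Loss of interest (synthetic fixture),depression_symptom
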