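code,display
404684003,Clinical finding (finding)
55342001,Neoplastic disease (disorder)
363346000,Malignant neoplastic disease (disorder)
254837009,Malignant neoplasm of breast (disorder)
363358000,Malignant neoplasm of lung (disorder)
93143009,Leukemia (disorder)
118600007,Malignant lymphoma (disorder)
702391001,Renal cell carcinoma (disorder)
363406005,Malignant neoplasm of colon (disorder)
109355002,Carcinoma in situ (disorder)
92695006,Carcinoma in situ of bronchus (disorder)
99741000119100,Adenocarcinoma in situ in villous adenoma (disorder)
126952004,Neoplasm of brain (disorder)
93727008,Primary malignant neoplasm of brain (disorder)
92030004,Benign neoplasm of brain (disorder)
92186001,Benign neoplasm of cerebral meninges (disorder)
20376005,Benign neoplastic disease (disorder)
416471007,Family history of clinical finding (situation)
275937001,Family history of cancer (situation)
84114007,Heart failure (disorder)
417996009,Systolic heart failure (disorder)
441530006,Chronic systolic heart failure (disorder)
418304008,Diastolic heart failure (disorder)
85898001,Cardiomyopathy (disorder)
195021004,Dilated cardiomyopathy (disorder)
38341003,Hypertensive disorder (disorder)
73211009,Diabetes mellitus (disorder)
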