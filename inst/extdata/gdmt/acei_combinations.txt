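# ACE-inhibitor combination products matched by drug name (synthetic
# stand-ins for the eight named combination medications).
lisinopril-hydrochlorothiazide
enalapril-hydrochlorothiazide
captopril-hydrochlorothiazide
quinapril-hydrochlorothiazide
fosinopril-hydrochlorothiazide
benazepril-amlodipine
trandolapril-verapamil
perindopril-amlodipine
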