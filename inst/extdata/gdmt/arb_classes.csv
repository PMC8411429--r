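title,level
Angiotensin Receptor Antagonists,class
Angiotensin Receptor Blockers,class
Angiotensin II Receptor Blockers (ARBs),class
Angiotensin II Receptor Antagonists,class
ARB-Diuretic Combinations,class
ARB-Calcium Channel Blocker Combinations,class
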