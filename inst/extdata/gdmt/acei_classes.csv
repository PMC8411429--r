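title,level
ACE Inhibitors,class
ACE Inhibitor-Diuretic Combinations,class
ACE Inhibitors,subclass
ACE Inhibitor & Calcium Channel Blocker Combinations,subclass
ACE Inhibitor & Thiazide Diuretic Combinations,subclass
ACE Inhibitor & Potassium-Sparing Diuretic Combinations,subclass
"ACE Inhibitors, Sulfhydryl-Containing",subclass
"ACE Inhibitors, Dicarboxylate-Containing",subclass
"ACE Inhibitors, Phosphonate-Containing",subclass
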