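# Evidence-based beta-blocker ingredients for reduced-EF cardiomyopathy.
# Matching is case-insensitive substring on the drug name; metoprolol
# matches only as succinate.
carvedilol
metoprolol succinate
bisoprolol
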