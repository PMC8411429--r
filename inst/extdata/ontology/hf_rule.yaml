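# HFrEF Problem-List rule: systolic heart failure and/or dilated
# cardiomyopathy, with descendants.
includes:
  - code: "417996009"
    with_descendants: true
  - code: "195021004"
    with_descendants: true
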