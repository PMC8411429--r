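# Broad cancer-population value-set rule: include malignant neoplastic
# disease, carcinoma in situ, adenocarcinoma in situ in villous adenoma and
# neoplasm of brain (each with descendants) AND NOT benign neoplasm of brain
# or family-history situation codes (each with descendants).
includes:
  - code: "363346000"
    with_descendants: true
  - code: "109355002"
    with_descendants: true
  - code: "99741000119100"
    with_descendants: true
  - code: "126952004"
    with_descendants: true
excludes:
  - code: "92030004"
    with_descendants: true
  - code: "416471007"
    with_descendants: true
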