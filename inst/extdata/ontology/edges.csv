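child_code,parent_code
55342001,404684003
363346000,55342001
254837009,363346000
363358000,363346000
93143009,363346000
118600007,363346000
702391001,363346000
363406005,363346000
109355002,55342001
92695006,109355002
99741000119100,109355002
126952004,55342001
93727008,126952004
93727008,363346000
92030004,126952004
92030004,20376005
92186001,92030004
20376005,55342001
275937001,416471007
84114007,404684003
417996009,84114007
441530006,417996009
418304008,84114007
85898001,404684003
195021004,85898001
38341003,404684003
73211009,404684003
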