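bone,min_grade,max_grade
radius,0,14
ulna,0,12
first_metacarpal,0,11
third_metacarpal,0,10
fifth_metacarpal,0,10
first_proximal_phalange,0,12
third_proximal_phalange,0,12
fifth_proximal_phalange,0,12
third_middle_phalange,0,12
fifth_middle_phalange,0,12
first_distal_phalange,0,11
third_distal_phalange,0,11
fifth_distal_phalange,0,11
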