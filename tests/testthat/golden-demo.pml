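# crosslink map for demo
# threshold 27.0 A: 2 satisfied, 1 violated, 1 missing; 2 mono-link(s)
set dash_width, 2.5
set dash_gap, 0.5
distance xl_1_A_3_A, /demo//A/1/CA, /demo//A/3/CA
color blue, xl_1_A_3_A
hide labels, xl_1_A_3_A
distance xl_3_A_5_A, /demo//A/3/CA, /demo//A/5/CA
color blue, xl_3_A_5_A
hide labels, xl_3_A_5_A
distance xl_1_A_6_A, /demo//A/1/CA, /demo//A/6/CA
color red, xl_1_A_6_A
hide labels, xl_1_A_6_A
# not shown (missing residue A/99): xl_1_A_99_A
show spheres, /demo//B/2/CA
set sphere_scale, 0.5, /demo//B/2/CA
color green, /demo//B/2/CA
# not shown (missing residue B/99): xlml_99_B
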