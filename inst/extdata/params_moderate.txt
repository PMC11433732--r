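# nalpbpk parameter set: moderate hepatic impairment (Child-Pugh B, 162 mg)
group: moderate
cl_int_h: 92
cl_nh: 4.14
f_m3: 0.35
f_m4: 0.1
f_m5: 0.55
cl_int_m3_to_m1: 40
cl_int_m4_to_m4g: 5
cl_gi_mult: 0.25
k_rel: 0.25
clf_observed: 142
v_nal: 267
v_nal_c: 60
v_nal_p1: 80
v_nal_p2: 127
q_nal_p1: 60
q_nal_p2: 20
v_m1: 53
v_m3: 214
v_m3_c: 15
q_m3_p: 20
v_m4: 214
v_m5: 15
v_m4g: 15
cl_elim_m1: 20
cl_elim_m3: 4
cl_elim_m4: 40
cl_elim_m5: 17
cl_elim_m4g: 0
cl_exch_met: 100
bp_nal: 1.15
bp_m1: 0.7
bp_m3: 0.9
bp_m4: 0.9
bp_m5: 0.56
bp_m4g: 0.56
mw_nal: 357.45
mw_m1: 403.43
mw_m3: 373.45
mw_m4: 373.45
mw_m5: 533.57
mw_m4g: 549.57
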