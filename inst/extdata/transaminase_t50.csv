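variant_id,mutations,activity,activity_sd
WT,,6.9,0.6
P1,I77L,20.1,0.6
P2,Q97E,16.5,0.6
P3,H210N,23.1,0.9
P4,N245D,14.8,0.6
P5,G292D,14.8,0.8
P6,I295V,9.3,0.5
P7,I77L_H210N,42.2,0.8
P8,Q97E_H210N,30.6,0.5
P9,H210N_N245D,18.4,0.6
P10,H210N_G292D,33.6,0.5
P11,I77L_Q97E_H210N,31,0.7
P12,I77L_H210N_G292D,16.7,0.6
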