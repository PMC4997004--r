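user_id,days,n_responded,n_success
s01,13,75,69
s02,10,56,47
s03,13,77,68
s04,9,51,38
s05,10,58,55
s06,5,30,28
s07,5,30,28
s08,5,30,23
s09,8,48,41
s10,8,48,45
s11,8,48,41
s12,8,48,42
s13,8,48,41
s14,8,48,40
s15,8,48,39
s16,10,60,50
s17,16,96,79
s18,16,96,83
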