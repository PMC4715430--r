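test	observed	total
phi_sc	7	29
phi_st	12	29
phi_ct	0	29
gst	3	31
gsi_east	7	31
gsi_west	6	31
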