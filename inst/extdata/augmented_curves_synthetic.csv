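curve_id,neuron,size_mode,sphere,cube,plate,cylinder,baseline,orientation_pref_deg,orientation_sd_deg
n1_sizesel,1,monotone,4,3,5,6,2,45,45
n1_sizeinv,1,invariant,4,3,5,6,2,45,45
n2_sizesel,2,monotone,10,30,15,8,5,90,45
n2_sizeinv,2,invariant,10,30,15,8,5,90,45
n3_sizesel,3,monotone,5,4,8,45,3,0,45
n3_sizeinv,3,invariant,5,4,8,45,3,0,45
n4_sizesel,4,monotone,35,12,10,18,5,0,45
n4_sizeinv,4,invariant,35,12,10,18,5,0,45
n5_sizesel,5,monotone,20,22,28,38,8,0,45
n5_sizeinv,5,invariant,20,22,28,38,8,0,45
n6_sizesel,6,monotone,6,7,40,42,5,90,45
n6_sizeinv,6,invariant,6,7,40,42,5,90,45
plate_cyl_equal,7,invariant,8,10,35,35,5,45,45
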