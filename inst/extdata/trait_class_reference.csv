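trait,class,label,frequency
inflorescence_color,1,green,0.965
inflorescence_color,2,purple,0.035
trichome,1,sparse,0.150
trichome,2,intermediate,0.255
trichome,3,dense,0.595
panicle_type,1,scattered,0.236
panicle_type,2,lateral,0.526
panicle_type,3,compact,0.238
axis_shape,1,erect,0.233
axis_shape,2,slightly_bent,0.541
axis_shape,3,bent,0.226
inflorescence_density,1,sparse,0.070
inflorescence_density,2,slightly_sparse,0.070
inflorescence_density,3,intermediate,0.417
inflorescence_density,4,slightly_dense,0.374
inflorescence_density,5,dense,0.069
projection_branch_base,1,absent,0.668
projection_branch_base,2,slight,0.200
projection_branch_base,3,obvious,0.132
branching_habit,1,absent,0.726
branching_habit,2,present,0.274
angle_divergence_branches,1,small,0.606
angle_divergence_branches,2,intermediate,0.270
angle_divergence_branches,3,large,0.124
branched_spike_length,1,short,0.327
branched_spike_length,2,intermediate,0.327
branched_spike_length,3,long,0.346
shatter_resistance,1,weak,0.444
shatter_resistance,2,intermediate,0.308
shatter_resistance,3,strong,0.248
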