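trait,abbrev,kind,unit,mean,cv_percent,diversity
tiller_number,TN,quantitative,count,2.26,31.54,1.95
main_stem_nodes,MSN,quantitative,count,6.34,16.80,NA
panicle_length,PL,quantitative,cm,37.05,21.43,NA
stem_height,SH,quantitative,cm,129.57,20.09,NA
stem_diameter,SD,quantitative,mm,6.79,22.12,2.10
panicle_weight_per_plant,PWP,quantitative,g,9.97,35.64,NA
grain_weight_per_plant,GWP,quantitative,g,7.20,37.37,2.08
straw_weight_per_plant,SWP,quantitative,g,32.15,60.03,NA
thousand_grain_weight,TGW,quantitative,g,7.09,14.94,NA
grain_length,GL,quantitative,mm,2.85,5.22,2.04
grain_width,GW,quantitative,mm,2.16,6.61,2.02
grain_length_width_ratio,LWR,quantitative,ratio,1.33,5.48,2.00
inflorescence_color,IC,qualitative,code,NA,NA,0.15
trichome,T,qualitative,code,NA,NA,NA
panicle_type,PT,qualitative,code,NA,NA,NA
axis_shape,AS,qualitative,code,NA,NA,NA
inflorescence_density,ID,qualitative,code,NA,NA,NA
projection_branch_base,PBB,qualitative,code,NA,NA,NA
branching_habit,BH,qualitative,code,NA,NA,NA
angle_divergence_branches,ADB,qualitative,code,NA,NA,NA
branched_spike_length,BSL,qualitative,code,NA,NA,NA
shatter_resistance,RS,qualitative,code,NA,NA,NA
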