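measure_id	region_label	d	log_vr
lh_thalamus_vol	Left thalamus	0.840	0.237
rh_thalamus_vol	Right thalamus	0.918	0.357
lh_caudate_vol	Left caudate	0.609	0.150
rh_caudate_vol	Right caudate	0.625	0.147
lh_putamen_vol	Left putamen	0.757	0.197
rh_putamen_vol	Right putamen	0.786	0.220
lh_pallidum_vol	Left pallidum	0.768	0.317
rh_pallidum_vol	Right pallidum	0.793	0.339
lh_hippocampus_vol	Left hippocampus	0.673	0.173
rh_hippocampus_vol	Right hippocampus	0.669	0.232
lh_amygdala_vol	Left amygdala	0.765	0.154
rh_amygdala_vol	Right amygdala	0.790	0.216
lh_accumbens_vol	Left accumbens	0.414	0.168
rh_accumbens_vol	Right accumbens	0.454	0.119
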