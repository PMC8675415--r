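measure_class	n_male_stronger	n_female_stronger
subcortical_volume	2	16
cortical_thickness	478	6
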