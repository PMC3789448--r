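acquisition	f_mel_pct	d_epi_mm	f_blood_pct	c_oxy_pct	d_dermis_mm
baseline	13.3	0.0149	1.6	71.9	1.02
occlusion	14.2	0.0145	2.8	55.4	1.01
reperfusion	13.5	0.0143	1.7	76.7	1.01
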