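region	path	orientation	index	I_p	I_t	delta_q	omega	omega_norm_reported
temporal	Row 100	row	100	1.2e-18	5.3e-19	0.3	2.7e-37	0.36
temporal	Row 125	row	125	1.0e-18	1.1e-18	0.8	1.8e-37	0.23
temporal	Row 150	row	150	1.1e-18	1.7e-18	1.1	2.1e-37	0.27
temporal	Column 60	column	60	1.8e-18	5.9e-18	2.2	7.7e-37	1
temporal	Column 70	column	70	9.7e-19	5.4e-18	3.8	1.7e-37	0.22
temporal	Column 80	column	80	6.8e-19	2.5e-18	2.5	7.6e-38	0.10
frontal	Row 45	row	45	2.8e-18	1.4e-17	3.4	2.1e-36	1
frontal	Row 60	row	60	2.0e-18	1.2e-17	4.1	9.4e-37	0.44
frontal	Row 75	row	75	1.5e-18	9.4e-18	4.1	5.0e-37	0.24
frontal	Column 90	column	90	5.0e-19	1.8e-18	2.5	3.8e-38	0.02
frontal	Column 120	column	120	4.0e-19	1.5e-18	2.6	2.2e-38	0.01
frontal	Column 150	column	150	4.5e-19	1.7e-18	2.6	3.1e-38	0.01
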