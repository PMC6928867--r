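gene	Spinal Cord	Cerebellum	Hippocampus	Brain Cortex
HOXA2	8.14	0	0	0
HOXA4	29.14	0.03	0	0.01
HOXA5	23.01	0.08	0.01	0.02
HOXB2	20.31	0.54	0.19	0.10
HOXB3	6.16	0.17	0.05	0.04
HOXB5	8.52	0	0	0
HOXB6	5.37	0	0	0
HOXB7	15.82	0	0.05	0.02
HOXB8	17.91	0	0	0
HOXD8	5.41	0	0	0.01
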