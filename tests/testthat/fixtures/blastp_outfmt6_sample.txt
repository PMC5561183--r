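protA	protA	100.000	77	0	0	1	77	1	77	7.58e-56	153
protA	protB	76.923	39	4	1	4	42	11	44	6.64e-18	57.0
protA	protB	73.333	30	8	0	44	73	10	39	1.46e-15	51.2
protB	protB	100.000	46	0	0	1	46	1	46	3.66e-33	94.4
protB	protA	76.923	39	4	1	11	44	4	42	3.96e-18	57.0
protB	protA	73.333	30	8	0	10	39	44	73	8.73e-16	51.2
protC	protC	100.000	42	0	0	1	42	1	42	4.14e-27	78.6
protC	protA	23.529	17	13	0	17	33	21	37	9.1	 9.6
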