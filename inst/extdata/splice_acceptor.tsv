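pos	A	C	G	T
-14	0.11	0.31	0.13	0.45
-13	0.10	0.32	0.11	0.47
-12	0.11	0.33	0.11	0.45
-11	0.09	0.30	0.12	0.49
-10	0.10	0.34	0.10	0.46
-9	0.12	0.32	0.10	0.46
-8	0.10	0.36	0.09	0.45
-7	0.09	0.38	0.09	0.44
-6	0.08	0.40	0.08	0.44
-5	0.08	0.42	0.07	0.43
-4	0.24	0.28	0.24	0.24
-3	0.03	0.76	0.01	0.20
-2	1.00	0.00	0.00	0.00
-1	0.00	0.00	1.00	0.00
1	0.24	0.14	0.49	0.13
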