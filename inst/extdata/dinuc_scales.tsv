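dinuc	ta_richness	minor_groove_width	melting
AA	0.80	0.10	0.747
AC	0.30	0.35	0.482
AG	0.30	0.30	0.578
AT	0.90	0.05	0.819
CA	0.30	0.55	0.476
CC	0.00	0.45	0.241
CG	0.00	0.65	0.042
CT	0.30	0.30	0.578
GA	0.30	0.40	0.566
GC	0.00	0.50	0.000
GG	0.00	0.45	0.241
GT	0.30	0.35	0.482
TA	1.00	0.60	1.000
TC	0.30	0.40	0.566
TG	0.30	0.55	0.476
TT	0.80	0.10	0.747
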