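stratum	condition	mean	ciLow	ciHigh
whole_genome	normal	4.09	3.31	4.90
whole_genome	high	5.80	4.35	7.44
whole_genome	low	5.68	4.13	7.38
gene	normal	4.52	3.23	5.92
gene	high	4.95	2.65	7.23
gene	low	4.92	3.94	5.90
intergenic	normal	3.84	2.94	4.81
intergenic	high	6.05	4.04	8.06
intergenic	low	5.85	4.01	7.87
AT	normal	3.60	2.91	4.34
AT	high	3.80	3.20	4.44
AT	low	3.76	2.88	4.69
CG	normal	4.58	3.34	6.01
CG	high	8.14	6.41	9.87
CG	low	7.85	5.81	10.1
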