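protein	k_t	sigma_k_t	k_in	sigma_k_in	k_out	sigma_k_out	n_in_bar	sigma_n_in_bar
tensin1	11.29	0.32	4.94	0.20	6.35	0.23	0.562	0.013
talin1	15.0	0.6	7.8	0.5	7.2	0.5	0.481	0.030
vinculin	17.7	0.7	5.2	0.4	12.5	0.6	0.706	0.021
alpha-actinin	25.7	1.4	6.1	0.6	19.6	1.2	0.761	0.020
ILK	23.4	1.2	9.3	0.6	14.1	0.8	0.603	0.017
alpha-parvin	26.1	1.5	10.7	0.8	15.4	1.0	0.590	0.018
kindlin2	28.8	1.8	10.6	0.9	18.1	1.3	0.630	0.022
paxillin	37.3	2.5	14.2	1.5	23.1	1.9	0.619	0.031
p130Cas	45.0	3.1	12.5	1.4	32.6	2.5	0.724	0.026
VASP	86	7	19.2	3.4	66	6	0.78	0.04
FAK	83	6	29.1	3.0	54	5	0.649	0.024
zyxin	87	6	14.9	2.2	72	6	0.829	0.021
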