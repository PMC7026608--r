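pair,class,nmr1,nmr2,md,rect
2C_H6-1C_H1',m,1.24,1.24,1.18,1.38
3U_H6-2C_H1',m,0.97,0.97,1.28,1.10
4C_H6-3U_H1',m,1.18,1.18,1.06,2.23
6U_H6-5G_H1',m,1.02,1.02,1.06,1.04
8G_H8-9U_H6,m,0.98,0.99,1.12,1.11
11G_H8-10G_H1',m,1.17,1.16,1.33,1.29
11G_H8-12U_H6,m,0.96,0.96,0.95,1.14
12U_H6-11G_H1',m,1.20,1.21,1.02,0.94
14G_H8-13U_H1',m,0.96,0.95,0.68,2.39
14G_H8-14G_H1',s,0.94,0.95,0.73,2.45
14G_H8-15U_H6,l,2.12,1.10,2.12,1.62
15U_H6-15U_H1',s,0.88,0.87,0.88,1.16
17A_H2-16G_H1',m,1.75,1.89,1.64,1.19
17A_H8-16G_H1',l,5.01,0.99,4.03,8.70
17A_H8-16G_H8,m,0.88,0.99,0.46,0.54
17A_H8-18A_H8,m,1.06,1.60,3.04,2.06
18A_H8-19C_H6,m,1.04,1.22,0.88,1.16
19C_H6-18A_H1',m,1.15,1.14,1.11,4.17
20C_H6-19C_H1',m,1.19,1.18,1.23,1.23
22C_H6-21A_H1',m,1.20,1.20,1.15,1.15
25U_H6-24A_H1',m,1.07,1.05,0.97,0.95
26G_H8-25U_H6,m,0.98,0.98,1.16,0.99
29G_H8-28G_H1',m,1.34,1.33,1.16,1.40
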