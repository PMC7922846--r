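age,qx
0,5.3e-4
1,5.328252285111563e-4
2,5.359165208936543e-4
3,5.392989335219975e-4
4,5.429998824368102e-4
5,5.470493655647051e-4
6,5.514802058655458e-4
7,5.563283173779303e-4
8,5.616329963193166e-4
9,5.674372396002941e-4
10,5.737880933347084e-4
11,5.807370341704779e-4
12,5.883403865319657e-4
13,5.96659779155855e-4
14,6.057626446209615e-4
15,6.157227659209092e-4
16,6.266208745098966e-4
17,6.385453046689935e-4
18,6.51592709496916e-4
19,6.658688443287201e-4
20,6.814894239323883e-4
21,6.985810604312923e-4
22,7.172822895548304e-4
23,7.377446935354846e-4
24,7.601341297539037e-4
25,7.846320750907558e-4
26,8.114370968819553e-4
27,8.407664624000436e-4
28,8.728578999073263e-4
29,9.079715255549277e-4
30,9.463919517461849e-4
31,9.884305940536528e-4
32,0.001034428195388366
33,0.0010847575878809334
34,0.001139826714860807
35,0.0012000819374282812
36,0.0012660116524205456
37,0.0013381502510970951
38,0.0014170824506315061
39,0.0015034480335183473
40,0.0015979470333103392
41,0.0017013454087186014
42,0.0018144812520672188
43,0.001938271582424577
44,0.0020737197784729718
45,0.0022219237113633855
46,0.0023840846434760496
47,0.0025615169652153926
48,0.0027556588487606935
49,0.0029680839051260503
50,0.0032005139390156546
51,0.0034548329048583893
52,0.003733102177142014
53,0.004037577258820119
54,0.004370726063221344
55,0.004735248917644305
56,0.005134100450776726
57,0.005570513541346616
58,0.006048025522120502
59,0.006570506851644425
60,0.007142192486125609
61,0.007767716205738625
62,0.008452148173586808
63,0.009201036031752041
64,0.010020449867535515
65,0.010917031414362035
66,0.011898047886144252
67,0.012971450881459571
68,0.014145940834985752
69,0.015431037538604213
70,0.01683715730377787
71,0.018375697390640492
72,0.02005912838813516
73,0.02190109529398603
74,0.02391652811380413
75,0.02612176287578455
76,0.028534674041876304
77,0.031174819388679057
78,0.0340635985323946
79,0.037224426382752106
80,0.04068292293183251
81,0.04446712091611954
82,0.04860769303497546
83,0.0531382005672544
84,0.05809536540120678
85,0.06351936768260527
86,0.0694541714936699
87,0.07594788120257255
88,0.08305313137190061
89,0.09082751338647148
90,0.0993340422585152
91,0.10864166739390135
92,0.1188258314594091
93,0.12996908188092238
94,0.14216173992902945
95,0.15550263281527957
96,0.17009989473308054
97,0.18607184333604745
98,0.2035479387580752
99,0.22266983294843634
100,1
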