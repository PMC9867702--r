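day,metric,mean,sd,n
0,fold,1.0,0.05,3
4,fold,1.86,0.093,3
7,fold,2.7,0.135,3
10,fold,2.78,0.139,3
11,fold,2.8,0.14,3
0,viability,0.76,0.02,3
4,viability,0.98,0.01,3
7,viability,0.99,0.01,3
11,viability,0.96,0.02,3
0,ki67,0.98,0.01,3
4,ki67,0.95,0.02,3
7,ki67,0.86,0.02,3
11,ki67,0.482,0.024,3
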