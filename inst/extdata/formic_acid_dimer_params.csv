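type_a,type_b,A,B,C,n,s,d
C,C,87222.68,4.52,-2614.24,6,10,1.8
C,O,18423.16,3.22,-4.76,10,10,1.7
C,OH,101988.82,3.76,-801.90,6,10,1.7
C,HO,-118682.03,5.31,49.92,4,10,1.2
C,HCO,-91515.91,5.31,5.68,2,10,1.2
O,O,157533.31,3.84,-249.70,9,10,1.7
O,OH,229576.11,3.74,-1494.51,6,10,1.7
O,HO,-12321.28,5.15,-106.36,3,10,1.0
O,HCO,7911.47,3.45,-735.00,9,10,1.2
OH,OH,282168.52,3.74,-1073.49,5,10,1.7
OH,HO,-3746.89,3.44,-49.80,4,10,1.0
OH,HCO,3900.44,2.91,-380.87,8,10,1.2
HO,HO,2029.79,3.07,27.04,2,10,1.0
HO,HCO,10653.65,4.26,-396.77,11,10,1.0
HCO,HCO,9870.51,3.49,-289.72,5,10,1.0
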