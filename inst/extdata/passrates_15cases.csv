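case,g33_with_gac,g33_without_gac,g22_with_gac,g22_without_gac
1,95.4,93.8,85.9,84.0
2,97.6,97.2,90.3,89.4
3,96.6,95.3,86.1,83.2
4,97.6,97.0,89.2,87.3
5,97.1,96.0,88.5,87.5
6,97.8,96.7,88.7,87.0
7,91.9,91.0,80.7,78.2
8,95.9,94.7,83.3,82.4
9,94.3,91.7,79.6,75.4
10,95.2,94.8,84.2,83.4
11,91.9,89.1,77.3,74.2
12,94.9,94.0,83.6,82.6
13,95.9,94.3,86.1,84.1
14,91.3,87.8,74.9,71.0
15,87.6,85.8,72.8,70.7
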