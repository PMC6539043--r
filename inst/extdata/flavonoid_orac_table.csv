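name,n_oh,ete1,pa1,bde1,he,ln_orac,ln_orac_sd
Genistein,3,89.175,33.630,83.987,-17.606,2.267,0.008
Naringenin,3,90.557,33.240,84.979,-19.251,2.141,0.014
Scutellarin,4,78.864,35.648,75.694,-17.513,2.042,0.014
"3,5,7,8,3',4'-Hexahydroxyflavone",6,67.389,42.831,71.402,-20.148,2.026,0.001
Epicatechin,5,68.664,49.233,79.080,-27.271,2.018,0.004
Kaempferol,4,84.259,33.472,78.913,-17.382,2.018,0.018
Eriodictyol,4,84.665,33.190,79.037,-21.559,2.013,0.006
Apigenin,3,89.514,35.499,86.196,-18.219,2.010,0.000
Quercetin,5,83.812,32.554,77.549,-19.749,1.970,0.003
Liquiritigenin,2,89.619,33.975,84.776,-19.203,1.970,0.003
Fisetin,4,84.471,33.907,79.560,-19.860,1.959,0.022
Taxifolin,5,85.166,32.360,78.708,-23.422,1.942,0.004
Hesperetin,3,85.930,33.240,80.352,-17.828,1.938,0.014
"3,3',4'-Trihydroxyflavone",3,73.742,43.939,78.863,-13.813,1.869,0.019
"7,3',4'-Trihydroxyflavone",3,84.339,34.749,80.271,-21.503,1.691,0.016
Diosmetin,3,87.176,33.782,82.141,-16.976,1.656,0.001
Luteolin,4,84.601,34.584,80.367,-20.391,1.611,0.013
Morin,5,70.199,47.284,78.665,-21.759,1.517,0.006
Epigallocatechin,6,78.699,35.785,75.666,-27.626,1.225,0.020
"5,3',4'-Trihydroxyflavone",3,84.893,34.572,80.647,-15.957,1.223,0.038
Ampelopsin,6,82.652,32.448,76.283,-25.878,1.204,0.038
Myricetin,6,81.442,33.218,75.843,-21.695,1.173,0.000
Wogonin,2,89.929,33.535,84.646,-11.865,1.077,0.000
"7,8-Dihydroxyflavone",2,84.537,32.175,77.894,-14.759,1.051,0.002
Chrysin,2,96.442,33.750,91.375,-13.037,1.016,0.001
Pinocembrin,2,97.500,33.197,91.879,-13.970,1.013,0.011
Catechin,5,68.136,49.725,79.043,-27.785,1.012,0.018
Eupatilin,2,92.534,33.579,87.295,-13.554,0.891,0.013
Baicalein,3,81.439,33.164,75.786,-12.133,0.816,0.003
Pectolinarigenin,2,92.425,33.712,87.319,-12.482,0.788,0.023
"3,5-Dihydroxyflavone",2,83.211,36.125,80.518,-7.727,0.767,0.046
Alpinetin,1,95.985,33.690,90.857,-17.037,0.492,0.009
Galangin,3,85.569,33.430,80.181,-12.605,0.328,0.030
Genkwanin,2,89.997,35.002,86.181,-14.537,-0.072,0.058
Primuletin,1,89.804,40.053,91.039,-8.315,-0.969,0.004
Tectochrysin,1,108.611,39.485,109.278,-9.220,-1.581,0.079
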