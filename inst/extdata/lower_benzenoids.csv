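name,e_pi,a,b,c,t2_num,t2_den,t3_num,t3_den
Benzene,8.0000,12,0,0,1,2,3,3
Naphthalene,13.6832,12,4,2,1,4,3,7
Anthracene,19.3137,12,8,4,1,6,3,11
Phenanthrene,19.4483,14,6,6,1,6,3,11
Tetracene,24.9308,12,12,6,1,8,1,5
Benzo[c]phenanthrene,25.1875,16,8,10,1,8,1,5
Benzo[a]anthracene,25.1012,14,10,8,1,8,1,5
Chrysene,25.1922,16,8,10,1,8,1,5
Triphenylene,25.2745,18,6,12,1,8,1,5
Pyrene,22.5055,12,8,10,1,8,1,5
Pentacene,30.5440,12,16,8,1,10,3,19
Benzo[a]tetracene,30.7255,14,14,10,1,10,3,19
"Dibenzo[a,h]anthracene",30.8805,16,12,12,1,10,3,19
"Dibenzo[a,j]anthracene",30.8795,16,12,12,1,10,3,19
Pentaphene,30.7627,14,14,10,1,10,3,19
Benzo[g]chrysene,30.9990,20,8,16,1,10,3,19
Pentahelicene,30.9362,18,10,14,1,10,3,19
Benzo[c]chrysene,30.9386,16,12,12,1,10,3,19
Picene,30.9432,18,10,14,1,10,3,19
Benzo[b]chrysene,30.8390,16,12,12,1,10,3,19
"Dibenzo[a,c]anthracene",30.9418,18,10,14,1,10,3,19
"Dibenzo[b,g]phenanthrene",30.8336,16,10,12,1,10,3,19
Perylene,28.2453,16,8,16,1,9,3,17
Benzo[e]pyrene,28.3361,16,8,16,1,9,3,17
Benzo[a]pyrene,28.2220,14,10,14,1,9,3,17
Hexahelicene,36.6814,12,12,24,1,11,1,7
Benzo[ghi]perylene,31.4251,14,10,20,1,10,3,19
Hexacene,36.1557,12,20,10,1,12,3,23
Coronene,34.5718,12,12,24,1,11,1,7
Ovalene,46.4974,8,16,38,1,15,3,29
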