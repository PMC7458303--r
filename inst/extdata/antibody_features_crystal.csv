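antibody,pdb_code,cavity_volume,h3_hydrophobic_area,gly_count,label
Adalimumab,4nyl,0,340,1,1
Panitumumab,5sx4,0,176,1,1
Ustekinumab,3hmw,0,310,0,1
Avelumab,4nki,518,285,2,1
Durvalumab,5x8m,536,482,1,1
Necitumumab,6b3s,138,327,1,1
Nivolumab,5wt9,334,157,1,1
Ramucirumab,3s34,338,114,0,1
Guselkumab,4m6n,556,220,0,1
Certolizumab,5wuv,1224,310,1,1
Daclizumab,3nfs,0,112,1,1
Efalizumab,3eo9,0,319,0,1
Natalizumab,4irz,506,374,1,1
Atezolizumab,5x8l,684,263,2,1
Obinutuzumab,3pp4,576,304,2,1
Canakinumab,4g5z,342,244,1,0
Ofatumumab,3giz,1173,452,1,0
Ipilimumab,5tru,0,274,1,0
Belimumab,5y9j,1425,584,1,0
Bevacizumab,1bj1,1045,556,1,0
Eculizumab,5i5k,1077,549,2,0
Omalizumab,4x7s,942,357,1,0
Palivizumab,2hwz,825,318,0,0
Trastuzumab,6bhz,731,256,1,0
Alemtuzumab,1bey,0,228,1,0
Pembrolizumab,5ggs,2081,410,2,0
Ibalizumab,3o2d,1524,414,1,0
Pertuzumab,1s78,0,251,2,0
Bezlotoxumab,4np4,0,295,1,0
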