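antibody,h3_hydrophobic_area,gly_count,label,reported_prediction
Golimumab,589,1,1,0
Alirocumab,165,3,1,1
Dupilumab,653,3,1,0
Olaratumab,581,1,1,0
Sarilumab,123,1,1,1
Elotuzumab,239,0,1,1
Ixekizumab,354,1,1,1
Mepolizumab,289,2,1,1
Reslizumab,262,1,1,0
Vedolizumab,463,0,1,1
Inotuzumab,304,1,1,1
Benralizumab,482,1,1,0
Tildrakizumab,126,1,1,1
Denosumab,456,3,0,0
Daratumumab,715,4,0,0
Evolocumab,215,1,0,0
Raxibacumab,334,3,0,1
Secukinumab,874,1,0,1
Burosumab,219,1,0,0
Tocilizumab,422,1,0,0
Gemtuzumab,178,1,0,1
Idarucizumab,510,2,0,0
Ocrelizumab,399,2,0,0
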