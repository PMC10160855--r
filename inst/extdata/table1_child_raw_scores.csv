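algorithm,cause,score,pct,n_total
insilicova,malaria,356.8,19.4,1841
insilicova,pneumonia,275.7,15.0,1841
insilicova,diarrhea,445.2,24.2,1841
insilicova,severe_malnutrition,75.6,4.1,1841
insilicova,hiv,58.3,3.2,1841
insilicova,other,199.6,10.8,1841
insilicova,other_infections,429.9,23.3,1841
eava,malaria,144.2,7.8,1841
eava,pneumonia,437.1,23.7,1841
eava,diarrhea,344.4,18.7,1841
eava,severe_malnutrition,148.3,8.1,1841
eava,hiv,116.1,6.3,1841
eava,other,106.6,5.8,1841
eava,other_infections,544.2,29.6,1841
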