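algorithm,cause,score,pct,n_total
insilicova,congenital_malformation,1.6,0.2,818
insilicova,infection,363.8,44.5,818
insilicova,ipre,221.6,27.1,818
insilicova,other,33.5,4.1,818
insilicova,prematurity,197.5,24.1,818
eava,congenital_malformation,29.1,3.6,818
eava,infection,479.5,58.6,818
eava,ipre,144.3,17.6,818
eava,other,32.7,4.0,818
eava,prematurity,132.3,16.2,818
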