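site,spcode,x_m,y_m,girth_cm
p01,Fagus_crenata,12.3,44.1,88.2
p01,Fagus_crenata,15.8,47.6,31.4
p01,Fagus_crenata,18.0,41.9,20.7
p01,Quercus_crispula,55.2,61.0,120.6
p01,Quercus_crispula,58.7,64.4,17.9
p01,Acer_japonicum,71.5,22.8,47.1
p01,Acer_japonicum,73.9,25.2,16.5
p01,Camellia_japonica,33.0,78.4,26.1
p02,Castanopsis_sieboldii,41.7,12.9,157.0
p02,Castanopsis_sieboldii,44.2,15.3,23.6
p02,Cleyera_japonica,80.1,55.5,18.8
p02,Eurya_japonica,82.6,58.0,15.7
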