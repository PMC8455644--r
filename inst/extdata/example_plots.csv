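plot_id,width,height,altitude,temperature,precipitation,snow_depth,forest_type,succession
p01,100,100,950,8.1,1750,0.62,DB,OG
p02,100,100,120,16.4,2300,0.00,EB,OS
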