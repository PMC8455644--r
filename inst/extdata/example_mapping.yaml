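# maps the package's standard stem-table column names to the headers
# used by an external deposit
plot_id: site
species: spcode
x: x_m
y: y_m
gbh: girth_cm
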