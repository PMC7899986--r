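# Hexagon colour-space contrast values for measured flower parts of the
# study population: green (achromatic) contrast and colour contrast
# (distance from the background locus), with the human colour category of
# each flower.
sample,flower,part,category,green_contrast,color_contrast
O1_sep,O1,sepal,1,0.267,0.345
O1_lab,O1,labellum,1,0.087,0.097
O2_lab,O2,labellum,2,0.091,0.133
O5_sep,O5,sepal,3,0.285,0.353
O5_lab,O5,labellum,3,0.188,0.294
O6_sep,O6,sepal,4,0.130,0.225
O6_lab,O6,labellum,4,0.163,0.033
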