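# Pairwise hexagon colour distances between measured flower parts and the
# corresponding observed probability of discrimination by a trichromatic
# hymenopteran under absolute conditioning. These 21 pairs calibrate the
# psychometric function.
sample_a,flower_a,part_a,sample_b,flower_b,part_b,distance,probability
O1_sep,O1,sepal,O1_lab,O1,labellum,0.274,0.842
O1_sep,O1,sepal,O6_sep,O6,sepal,0.130,0.840
O1_lab,O1,labellum,O6_sep,O6,sepal,0.157,0.842
O1_sep,O1,sepal,O6_lab,O6,labellum,0.333,0.842
O1_lab,O1,labellum,O6_lab,O6,labellum,0.066,0.505
O6_sep,O6,sepal,O6_lab,O6,labellum,0.208,0.842
O1_sep,O1,sepal,O5_sep,O5,sepal,0.011,0.500
O1_lab,O1,labellum,O5_sep,O5,sepal,0.284,0.842
O6_sep,O6,sepal,O5_sep,O5,sepal,0.137,0.841
O6_lab,O6,labellum,O5_sep,O5,sepal,0.341,0.842
O1_sep,O1,sepal,O5_lab,O5,labellum,0.056,0.500
O1_lab,O1,labellum,O5_lab,O5,labellum,0.222,0.842
O6_sep,O6,sepal,O5_lab,O5,labellum,0.074,0.570
O6_lab,O6,labellum,O5_lab,O5,labellum,0.278,0.842
O5_sep,O5,sepal,O5_lab,O5,labellum,0.063,0.500
O1_sep,O1,sepal,O2_lab,O2,labellum,0.238,0.842
O1_lab,O1,labellum,O2_lab,O2,labellum,0.036,0.500
O6_sep,O6,sepal,O2_lab,O2,labellum,0.121,0.837
O6_lab,O6,labellum,O2_lab,O2,labellum,0.097,0.781
O5_sep,O5,sepal,O2_lab,O2,labellum,0.248,0.842
O5_lab,O5,labellum,O2_lab,O2,labellum,0.185,0.842
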