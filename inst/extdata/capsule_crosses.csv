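# Artificial cross-pollination outcomes between colour categories (unordered
# combination cells): percentage of evaluable crosses (grazed, lost and moldy
# capsules excluded) that formed a capsule, number evaluable, and seed
# viability (FDA test, mean +/- SE) where assayed.
category_a,category_b,capsule_pct,n_evaluable,viability_mean,viability_se
1,1,100,7,60,1
1,2,71,7,53,17
1,3,100,6,82,3
1,4,100,7,60,3
1,5,100,2,54,7
2,2,100,6,60,13
2,3,100,8,51,14
2,4,100,6,55,10
2,5,100,7,45,15
3,3,86,7,45,14
3,4,83,6,30,14
3,5,33,3,20,20
4,4,100,2,19,19
4,5,100,2,79,15
5,5,100,1,89,NA
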