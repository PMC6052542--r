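name,C,H,O,N,thod,carbon_count,acid_flag,solubility_g_per_L,source
glucose,6,12,6,0,,6,FALSE,,formula
xylose,5,10,5,0,,5,FALSE,,formula
formic,1,2,2,0,,1,TRUE,,formula
acetic,2,4,2,0,,2,TRUE,,formula
propionic,3,6,2,0,,3,TRUE,,formula
butyric,4,8,2,0,,4,TRUE,,formula
pentanoic,5,10,2,0,,5,TRUE,,formula
hexanoic,6,12,2,0,,6,TRUE,10.8,formula
heptanoic,7,14,2,0,,7,TRUE,2.4,formula
octanoic,8,16,2,0,,8,TRUE,0.68,formula
ethanol,2,6,1,0,,2,FALSE,,formula
glycerol,3,8,3,0,,3,FALSE,,formula
lactic,3,6,3,0,,3,FALSE,,formula
acetamide,2,5,1,1,,2,FALSE,,formula
2-octanol,8,18,1,0,,8,FALSE,,formula
protein,0,0,0,0,1.5,0,FALSE,,paper_fixed
carbohydrate,0,0,0,0,1.06,0,FALSE,,paper_fixed
other_carbohydrates,0,0,0,0,1.06,0,FALSE,,paper_fixed
unknown,0,0,0,0,1.0,0,FALSE,,paper_fixed
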