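phrase,kcal_per_100g,healthy,fastfood
coffee,1,FALSE,FALSE
beer,43,FALSE,FALSE
pizza,266,FALSE,FALSE
wine,83,FALSE,FALSE
chicken,239,TRUE,FALSE
ice cream,207,FALSE,FALSE
sushi,130,TRUE,FALSE
taco,226,FALSE,FALSE
salad,17,TRUE,FALSE
banana,89,TRUE,FALSE
eggs,155,FALSE,FALSE
turkey,189,TRUE,FALSE
apple,52,TRUE,FALSE
orange,47,TRUE,FALSE
orange chicken,146,FALSE,FALSE
fried chicken,245,FALSE,FALSE
grilled salmon,208,TRUE,FALSE
almonds,579,TRUE,FALSE
spinach,23,TRUE,FALSE
broccoli,34,TRUE,FALSE
burger,295,FALSE,FALSE
fries,312,FALSE,FALSE
donut,452,FALSE,FALSE
cupcake,305,FALSE,FALSE
chocolate,546,FALSE,FALSE
brownie,466,FALSE,FALSE
pasta,131,FALSE,FALSE
rice,130,FALSE,FALSE
tuna,132,TRUE,FALSE
yogurt,59,TRUE,FALSE
mcdonalds,257,FALSE,TRUE
starbucks,120,FALSE,TRUE
taco bell,218,FALSE,TRUE
burger king,263,FALSE,TRUE
kfc,246,FALSE,TRUE
chipotle,180,FALSE,TRUE
wendys,250,FALSE,TRUE
subway,212,FALSE,TRUE
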