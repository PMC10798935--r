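"id","name","cuisine","ingredient_classes","protein","lipids","carbohydrates","cholesterol","sodium","saturated_fat","calories","rating"
"r00001","Thai salmon dish 1","thai","salmon;walnuts;eggs;peanuts",82.36,20.73,24.25,151.65,2205.31,43.45,320.1,3.52
"r00002","Italian plum tomato dish 2","italian","plum_tomato;onions;cheddar",8.9,10.5,131.85,5.25,256.66,0.71,460.5,3.96
"r00003","Mexican onions dish 3","mexican","onions;chickpeas;plum_tomato;mushrooms;turkey;peanuts;lamb;almonds;cheddar;pork",12.2,14.36,80.38,1.22,246.07,46.75,892.4,4.76
"r00004","Thai yogurt dish 4","thai","yogurt;eggs;olive_oil",5.11,235.56,45.91,3.28,1210.76,0.24,793.1,3.04
"r00005","French milk dish 5","french","milk;kale;olive_oil;yogurt;tuna;turkey;lentils;basil;blueberry;corn",7.27,8,101.97,1.83,54.68,2.75,568.4,3.92
"r00006","Indian bananas dish 6","indian","bananas;mozzarella;plum_tomato;yogurt;mushrooms;zucchini",2.75,11.39,139.18,40.83,377.84,0.72,1502.5,3.04
"r00007","Turkish almonds dish 7","turkish","almonds;beef;kale",54.78,13.57,83.46,585.31,295.98,17.75,481.1,4.34
"r00008","Indian chili dish 8","indian","chili;chicken;corn",295.02,6.01,6.42,1.34,1757.55,14.99,454.5,3.35
"r00009","Turkish plum tomato dish 9","turkish","plum_tomato;turkey;beans;corn;beef",2.66,13.37,72.44,4.97,4976.92,0.72,723.2,4.58
"r00010","Indian mozzarella dish 10","indian","mozzarella;peppers;cheddar;honey;orange",20.11,1.5,237.97,1.59,276.3,4.14,514.6,3.43
"r00011","Mexican butter dish 11","mexican","butter;bananas;onions",36.25,5.67,111.38,28.76,68.69,2.82,1502.8,2.66
"r00012","Italian tuna dish 12","italian","tuna;kale;chickpeas;corn;rice;eggs",6.22,34.38,644.67,282.36,120.87,1.7,796.5,4.15
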