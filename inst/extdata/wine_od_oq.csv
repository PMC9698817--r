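"OD","Almond","Cooked","Cut-grass","Floral","Fresh","Fruity","Green","Honey","Lactony","Leather","Peel","Smoky","Spicy","Sulfurous","Toasty","Vanilla","Vegetable","Violet","Wine-like","Woody"
"almond",1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"banana",0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"buttery",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"cognac",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"ethereal",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"ethereal-fruity",0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"fruity",0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"juicy",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"pineapple",0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"ripe fruit",0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"tonka",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0
"vanilla",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0
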