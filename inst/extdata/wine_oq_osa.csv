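"OQ","Bell pepper","Blackcurrant bud","Blackcurrant fresh","Cherry cooked","Cherry fresh","Cherry stone","Cut-grass","Leather","Prune","Smoky","Strawberry fresh","Toasty","Vanilla","Violet","Woody"
"Almond",0,0,0,1,1,1,0,0,1,0,0,0,0,0,0
"Cooked",0,0,0,1,1,1,0,0,1,0,1,0,0,0,0
"Cut-grass",0,0,0,0,0,0,1,0,0,0,0,0,0,0,0
"Floral",1,1,1,1,1,1,0,0,0,0,1,0,0,0,0
"Fresh",1,1,1,0,0,0,0,0,0,0,0,0,0,0,0
"Fruity",0,1,1,0,0,0,0,0,1,0,1,0,0,0,0
"Green",1,1,1,1,1,1,0,0,0,0,1,0,0,0,0
"Honey",0,0,0,0,0,0,0,0,1,0,0,0,0,0,0
"Lactony",0,0,0,0,0,0,0,0,1,0,0,0,0,0,0
"Leather",0,0,0,0,0,0,0,1,0,0,0,0,0,0,0
"Peel",0,0,0,1,1,1,0,0,0,0,0,0,0,0,0
"Smoky",0,0,0,0,0,0,0,0,0,1,0,0,0,0,0
"Spicy",0,0,0,1,1,1,0,0,0,0,0,0,0,0,0
"Sulfurous",1,1,1,0,0,0,0,0,0,0,0,0,0,0,0
"Toasty",1,0,0,0,0,0,0,0,0,0,0,1,0,0,0
"Vanilla",0,1,0,0,0,0,0,0,0,0,0,0,1,0,0
"Vegetable",1,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"Violet",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"Wine-like",0,1,1,0,0,0,0,0,0,0,0,0,0,0,0
"Woody",0,0,0,0,0,0,0,0,0,0,0,0,0,0,1
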