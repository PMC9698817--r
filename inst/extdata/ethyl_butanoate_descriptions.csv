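"odorant_id","source_id","text"
"Ethyl butanoate (CAS 105-54-4)","Arctander","Powerful, ethereal-fruity odor suggestive of banana and pineapple, and very diffusive"
"Ethyl butanoate (CAS 105-54-4)","Flavor-Base","ethereal, fruity, buttery, pineapple, banana, ripe fruit, juicy"
"Ethyl butanoate (CAS 105-54-4)","GoodScents","fruity, juicy, pineapple, cognac"
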