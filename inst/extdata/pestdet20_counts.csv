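category_id,name,train_images,test_images,train_boxes,test_boxes
0,Rice leaf roller,131,34,141,38
3,Rice stem borer,126,33,138,34
14,Grub,331,80,532,108
15,Mole cricket,400,80,400,80
16,Wireworm,325,80,405,104
21,Red spider,125,31,128,36
24,Aphid,400,80,400,80
25,White-spotted flower beetle,145,40,173,46
26,Peach borer,188,45,199,47
37,Flea beetle,253,65,285,70
39,Beet armyworm,317,81,322,81
48,Acridoidea,400,80,400,80
50,Blister beetle,338,85,366,94
66,Grape hawkmoth,197,53,197,53
67,Cicada,253,63,253,63
70,Lycophoridae,400,80,400,80
76,Cotton scale,121,28,216,55
95,Brown-margined moth,134,33,142,36
99,Spine-chested longhorn beetle,92,26,93,27
101,Cicadidae,400,80,400,80
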