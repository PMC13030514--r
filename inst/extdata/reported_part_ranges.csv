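species,part,r_min,r_max,lambda_min,lambda_max
Convolvulus arvensis,General,5,15,500,780
Convolvulus arvensis,Body,5,45,500,780
Convolvulus arvensis,Root,20,35,550,780
Convolvulus arvensis,Root collar,25,30,550,780
Convolvulus arvensis,Leaf,10,31,550,780
Convolvulus arvensis,Stem,20,30,550,780
Erigeron canadensis,General,8,23,500,780
Erigeron canadensis,Body,5,45,500,780
Erigeron canadensis,Root,19,30,550,780
Erigeron canadensis,Leaf,7,30,550,780
Erysimum cheiranthoides,General,6,16,500,780
Erysimum cheiranthoides,Body,5,40,500,780
Erysimum cheiranthoides,Flower,20,35,500,780
Erysimum cheiranthoides,Stem,18,30,500,780
Erysimum cheiranthoides,Leaf,10,25,500,780
Sonchus arvensis,General,11,25,500,780
Sonchus arvensis,Body,3,35,500,780
Sonchus arvensis,Root,19,30,500,780
Sonchus arvensis,Stem,15,30,500,780
Sonchus arvensis,Leaf,15,28,500,780
Capsella bursa-pastoris,General,14,21,500,780
Capsella bursa-pastoris,Body,10,50,500,780
Capsella bursa-pastoris,Leaf,15,45,500,780
Capsella bursa-pastoris,Flower,22.5,30,500,780
Capsella bursa-pastoris,Stem,15,22.5,500,780
Artemisia vulgaris,General,8,19,500,780
Artemisia vulgaris,Body,10,55,500,780
Artemisia vulgaris,Root collar,15,40,550,780
Artemisia vulgaris,Root,15,30,550,780
Artemisia vulgaris,Stem,15,25,550,780
Artemisia vulgaris,Leaf,10,28,500,780
Ambrosia artemisiifolia,General,6,21,500,780
Ambrosia artemisiifolia,Body,3,35,500,780
Ambrosia artemisiifolia,Leaf,15,29,500,780
Ambrosia artemisiifolia,Stem,10,25,500,780
Amaranthus retroflexus,General,9,26,500,780
Amaranthus retroflexus,Body,7.5,43,500,780
Amaranthus retroflexus,Root,20,40,550,780
Amaranthus retroflexus,Stem,20,25,550,780
Amaranthus retroflexus,Leaf,10,25,550,780
Chenopodium album,General,14,25,500,780
Chenopodium album,Body,7,55,500,780
Chenopodium album,Leaf,22.5,45,500,780
Chenopodium album,Stem,22,25,550,780
Chenopodium album,Root,10,22.5,500,780
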