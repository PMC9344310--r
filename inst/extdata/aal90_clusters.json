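{"central":[1,2,19,20,57,58,69,70],"frontal":[3,4,5,6,7,8,9,10,11,12,13,14,15,16,21,22,23,24,25,26,27,28],"limbic":[29,30,31,32,33,34,35,36,37,38,39,40,41,42],"occipital":[43,44,45,46,47,48,49,50,51,52,53,54,55,56],"parietal":[59,60,61,62,63,64,65,66,67,68],"deep_grey":[71,72,73,74,75,76,77,78],"temporal":[17,18,79,80,81,82,83,84,85,86,87,88,89,90],"atlas_size":90,"index_base":1}
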