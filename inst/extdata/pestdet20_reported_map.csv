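method,shot,base,novel,all
yolo,3,79.4,53.2,66.3
yolo,5,77.2,73.8,75.5
yolo,10,77.8,77.2,77.5
tfa,3,85.2,45.3,75.3
tfa,5,85.1,51.9,76.9
tfa,10,84.9,60.1,78.7
vfa,3,78.7,51.3,71.9
vfa,5,80.7,59.9,75.6
vfa,10,84.9,60.1,78.7
fsce,3,81.6,54.8,74.9
fsce,5,82.4,61.8,77.2
fsce,10,82.5,71.6,79.8
ours,3,83.5,60,75.9
ours,5,82.6,70.1,79.5
ours,10,83.7,79.2,82.6
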