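category_id,role,yolo_3,yolo_5,yolo_10,tfa_3,tfa_5,tfa_10,vfa_3,vfa_5,vfa_10,fsce_3,fsce_5,fsce_10,ours_3,ours_5,ours_10
0,base,82.5,84.4,87,96,96,95.8,90.2,97.9,90.4,91.7,92.1,92,90.7,89.8,96.2
48,base,59.6,61.2,57.9,68.5,69,69.8,63.4,67,69.2,65.6,68,66.6,67,66.7,63.6
14,base,83,89.7,86.2,95.4,92.9,89.5,88.4,88.7,88.5,95.9,94.5,88,89.2,87.7,88.3
99,base,80.8,75.3,68.9,85.2,85,84.8,86.8,88.2,89.1,75.4,77.5,82.5,78.4,81.7,76.7
3,base,85.9,77,79.3,69.6,71.3,71.4,72.6,77.4,75,66.3,74.3,71.5,69.9,76.1,80.3
21,base,77.6,80.5,83.8,89,88.8,88.8,74.7,72.8,73.7,85.3,80.9,81,87.8,87.3,86.7
39,base,84.8,76.4,79.6,88,88,93.3,88.2,88.4,89.3,83.8,85.7,86.6,89.8,89.1,89.3
66,base,95.1,96.4,97.8,89.7,90,89.9,89.1,89.1,89.1,92.9,93.5,89.9,94.9,90.4,90.7
16,base,67.2,72.8,68.9,84.3,84.4,80.9,67.7,66.5,70.7,78.8,80.2,79.4,81.4,79.3,83.8
37,base,79.2,77.4,71.8,99.4,99.3,97.8,88,88.1,88.4,89,89.6,93.8,88.9,89.1,90.4
50,base,82.8,73.8,80.7,85.1,85.5,86.1,86.5,87.4,88.1,83,84.1,84.5,83.8,79.1,85.9
26,base,80.7,80,81.6,84.6,83.7,83.1,66.6,71.6,78.6,80.3,77.7,78.8,84.8,80.4,85.7
25,base,82.8,83.3,86.4,89,89.3,89.2,81.8,84.6,88.8,89.2,89.3,88.4,87.9,88.6,90.5
70,base,63.2,54.4,57.9,67.8,67.7,66.1,52.8,59.3,66.2,68.8,73.2,71.5,73.6,70.6,62.8
24,base,85.8,75.4,79.5,87.6,86.7,87.7,84.9,84.5,84.5,78.4,76.5,83.8,84.8,84.1,85.7
67,novel,72.7,98.2,98.5,81.8,82.7,83.3,92.1,94,96.5,90.9,90.1,94.4,90.9,95,97.6
101,novel,63.9,81.6,88.8,17,25.7,49,38.5,55.3,67.7,18.7,36.9,66.7,35.9,65,82.5
76,novel,17.3,23.8,36.8,12,27.8,28.8,17.2,28.8,33.7,28.3,33.1,34.6,30.1,36.8,44.9
15,novel,51.4,85.9,89.4,65,64.8,75.2,66.6,83.2,88.3,68.9,79.8,89.7,69,77.9,87.7
95,novel,60.5,79.3,72.4,51.2,58.6,64.4,42.5,38.4,57.4,67.5,68.1,72.8,74.1,76.1,83.5
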