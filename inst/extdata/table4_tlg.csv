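patient,location,tlg_40,tlg_50
1,Right breast cancer in the inner pericentral area,5794,4551
2,Right breast cancer in the upper pericentral area,1714,1382
3,Right breast cancer in the upper outer area,1185,889
4,Right breast cancer in the lower center area,1898,1296
5,Left breast cancer in the upper outer area,2052,1004
6,Right breast cancer in the lower pericentral area,3098,1893
7,Right breast cancer in the lower pericentral area,3513,2586
8,Right breast cancer in the upper outer area,1358,733
9,Metastatic lymph node in the right axilla,383,275
10,Left breast cancer in the upper outer area,2909,2216
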