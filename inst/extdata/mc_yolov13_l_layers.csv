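id,from,params,module,args
0,-1,464,Conv,"3,16,3,2"
1,-1,2368,Conv,"16,32,3,2,1,2"
2,-1,6424,C3k2_MSLA,"32,64,1,False,0.25"
3,-1,9344,Conv,"64,64,3,2,1,4"
4,-1,23724,C3k2_MSLA,"64,128,1,False,0.25"
5,-1,17792,DSConv,"128,128,3,2"
6,-1,174720,A2C2f,"128,128,2,True,4"
7,-1,34432,DSConv,"128,256,3,2"
8,-1,677120,A2C2f,"256,256,2,True,1"
9,-1,1121792,CMUNeXt,"256,256,1"
10,4;6;8,273536,HyperACE,"128,128,1,4,True,True,0.5,1,both"
11,-1,0,Upsample,"None,2,nearest"
12,10,33280,DownsampleConv,"128"
13,6;10,1,FullPAD_Tunnel,""
14,4;11,1,FullPAD_Tunnel,""
15,9;12,1,FullPAD_Tunnel,""
16,-1,0,Upsample,"None,2,nearest"
17,-1;13,0,Concat,"1"
18,-1,96600,C3k2_MSLA,"384,128,1,True"
19,-1;10,1,FullPAD_Tunnel,""
20,18,0,Upsample,"None,2,nearest"
21,-1;14,0,Concat,"1"
22,-1,29232,C3k2_MSLA,"256,64,1,True"
23,11,8320,Conv,"128,64,1,1"
24,22;23,1,FullPAD_Tunnel,""
25,-1,36992,Conv,"64,64,3,2"
26,-1;19,0,Concat,"1"
27,-1,72024,C3k2_MSLA,"192,128,1,True"
28,-1;10,1,FullPAD_Tunnel,""
29,27,147712,Conv,"128,128,3,2"
30,-1;15,0,Concat,"1"
31,-1,280232,C3k2_MSLA,"384,256,1,True"
32,-1;12,1,FullPAD_Tunnel,""
33,24;28;32,431452,Detect,"4,[64;128;256]"
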