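scenario,pattern1,pattern2,pattern3,rgi
1,15529,16516,7423,2.22
2,15041,16516,7423,2.22
3,14484,16516,7423,2.22
4,14814,16516,8100,2.04
5,15529,16516,7423,2.22
6,15529,16516,8781,2.35
7,15403,16516,8100,2.04
8,14590,16250,7423,2.19
9,16104,16516,8184,2.02
10,14610,15411,7592,2.18
11,15878,16533,9681,2.15
12,16104,16403,8201,2.00
13,15894,16516,7522,2.20
14,17345,15882,11235,2.42
15,17718,18150,12111,2.30
16,19001,18265,13404,2.21
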