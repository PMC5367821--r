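scenario,n_units,shape,net_profit,gain_ratio
1,1,square,7423,1.00
2,2,row,9954,1.34
3,2,column,8003,1.08
4,3,row,11009,1.48
5,3,column,15157,2.04
6,4,square,20672,2.78
7,6,row,13765,1.85
8,6,column,15157,2.04
9,9,row,16104,2.17
10,9,column,16516,2.22
11,9,square,20816,2.80
12,18,row,15918,2.14
13,18,column,16516,2.22
14,36,square,27148,3.66
15,81,square,27915,3.76
16,324,square,29615,3.99
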