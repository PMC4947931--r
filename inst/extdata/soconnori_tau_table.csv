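population,marker,tau,T_ma
Shigatse,cytb,6.178,0.135
Zhaxue,cytb,7.117,0.156
Quxu,cytb,5.395,0.118
Shannan,cytb,5.816,0.127
Mainling,cytb,6.219,0.136
Paizhen,cytb,5.938,0.130
Mean,cytb,6.111,0.134
Shigatse,cr,6.816,0.066
Zhaxue,cr,6.676,0.065
Quxu,cr,7.230,0.070
Shannan,cr,8.141,0.079
Mainling,cr,6.338,0.062
Paizhen,cr,6.863,0.067
Mean,cr,7.011,0.068
Shigatse,cytb_cr,14.248,0.114
Zhaxue,cytb_cr,12.152,0.097
Quxu,cytb_cr,11.928,0.095
Shannan,cytb_cr,13.090,0.104
Mainling,cytb_cr,10.941,0.087
Paizhen,cytb_cr,11.711,0.093
Mean,cytb_cr,12.345,0.098
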