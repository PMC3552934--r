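group,y,w
1,-1.9771,2.087
1,-2.1596,
1,-3.2688,
1,-2.1868,0.159
1,-2.3823,
1,-1.6108,1.1099
1,-2.8893,-0.7969
1,-3.0613,
1,-2.7936,
1,-1.681,-2.1668
1,-3.2987,
1,-1.6975,-0.2911
2,-2.3063,1.3538
2,-1.7452,
2,-0.9201,-1.8975
2,-2.7274,0.1641
2,-3.2669,
2,-1.2164,
2,-1.8971,-1.4787
2,-2.6173,
2,-1.0334,
2,-3.0231,1.4459
2,-2.4042,1.9186
2,-0.1561,
3,-0.8037,
3,-1.3875,
3,-0.0523,
3,-1.4625,
3,-1.3656,-0.9698
3,-0.7352,
3,-3.232,-1.1832
3,-1.8793,0.1794
3,0.5161,
3,-0.2357,2.2189
3,-2.6432,0.8007
3,-4.621,-0.359
4,-1.2624,0.5369
4,-2.0895,
4,-2.5152,0.6368
4,-1.2782,
4,-0.1338,
4,-1.6737,1.4076
4,-1.5593,
4,0.3504,2.717
4,-2.3286,-0.7218
4,-2.2726,1.4657
4,-1.4565,
4,-3.24,
5,-0.2086,
5,1.067,2.0986
5,-2.0774,0.0559
5,-0.832,1.6022
5,-2.2198,0.4034
5,-1.6112,
5,-1.3401,
5,-0.7571,
5,-0.1298,
5,-1.4696,
5,-0.6323,1.9877
5,-1.966,2.0162
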