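"kappa","mean_isi_ms","cv"
1,5,1.00203118147792
2,5,0.707639317197564
4,5,0.498410643038807
9,5,0.333386479517094
16,5,0.249688074432539
25,5,0.200176861665157
44,5,0.150424351832501
64,5,0.124846822434453
100,5,0.0998583180683288
200,5,0.0706628526891717
1,10,1.00197897280592
2,10,0.705628291662133
4,10,0.502938100986726
9,10,0.334442547556734
16,10,0.250408065133235
25,10,0.20096082679721
44,10,0.150165054110862
64,10,0.12575150046147
100,10,0.100224368490451
200,10,0.0710648873209138
1,15,0.991779318335273
2,15,0.706516745696278
4,15,0.499192916569711
9,15,0.334380604963588
16,15,0.249493043358271
25,15,0.19923339113493
44,15,0.150120089902904
64,15,0.124827904544187
100,15,0.0993523017408616
200,15,0.0703312648704511
1,20,0.998572021290629
2,20,0.702890010224263
4,20,0.502285577093049
9,20,0.334331460661472
16,20,0.249511800337695
25,20,0.200308597814866
44,20,0.150832295304785
64,20,0.125325694257228
100,20,0.0999207137873615
200,20,0.0709235242141678
1,30,1.00190704590623
2,30,0.705602264267068
4,30,0.499409172487264
9,30,0.334346561674825
16,30,0.25067118548005
25,30,0.200584019774404
44,30,0.150930361431212
64,30,0.124837901745109
100,30,0.0991038768167972
200,30,0.070727467894701
1,50,0.999251036584932
2,50,0.706141195513148
4,50,0.498227363380943
9,50,0.333733928649225
16,50,0.248577831822432
25,50,0.200597358559301
44,50,0.149973411566222
64,50,0.12410318859452
100,50,0.0999996143976526
200,50,0.0707303998565836
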