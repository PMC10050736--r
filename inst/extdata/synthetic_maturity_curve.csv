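sex,total_score,age_years
male,0,0
male,1,0.188
male,2,0.308
male,3,0.402
male,4,0.514
male,5,0.67
male,6,0.762
male,7,0.814
male,9,0.906
male,10,1.058
male,11,1.168
male,14,1.224
male,15,1.334
male,16,1.512
male,17,1.758
male,18,1.914
male,19,1.97
male,20,2.114
male,21,2.238
male,22,2.302
male,24,2.406
male,25,2.46
male,28,2.518
male,29,2.672
male,30,2.782
male,31,2.96
male,32,3.162
male,33,3.318
male,34,3.482
male,35,3.582
male,36,3.694
male,40,3.802
male,42,3.86
male,43,3.912
male,44,4.114
male,45,4.322
male,46,4.402
male,47,4.528
male,48,4.782
male,49,4.968
male,50,5.016
male,53,5.098
male,54,5.206
male,55,5.262
male,56,5.314
male,58,5.406
male,59,5.48
male,60,5.636
male,61,5.918
male,62,6.096
male,63,6.15
male,64,6.246
male,67,6.378
male,68,6.594
male,69,6.774
male,71,6.826
male,73,6.882
male,74,6.934
male,75,7.048
male,76,7.204
male,77,7.438
male,80,7.616
male,81,7.664
male,82,7.82
male,83,7.956
male,84,8.112
male,85,8.302
male,87,8.394
male,88,8.446
male,89,8.502
male,90,8.572
male,91,8.684
male,92,8.772
male,93,8.832
male,96,9.008
male,97,9.232
male,98,9.388
male,99,9.594
male,100,9.762
male,101,9.814
male,103,9.906
male,104,10.014
male,105,10.124
male,108,10.18
male,109,10.226
male,110,10.334
male,111,10.404
male,112,10.518
male,113,10.782
male,114,10.958
male,115,11.114
male,116,11.302
male,118,11.406
male,119,11.46
male,122,11.518
male,123,11.64
male,124,11.738
male,125,11.794
male,126,11.932
male,127,12.086
male,128,12.162
male,129,12.318
male,130,12.526
male,131,12.682
male,135,12.802
male,137,12.906
male,138,13.114
male,139,13.306
male,140,13.358
male,141,13.414
male,142,13.54
male,143,13.654
male,144,13.81
male,145,13.968
male,146,14.016
male,149,14.142
male,151,14.302
male,153,14.406
male,154,14.614
male,155,14.874
male,156,15.036
male,157,15.11
male,158,15.15
male,159,15.246
male,163,15.378
male,164,15.594
male,165,15.774
male,166,15.826
male,168,15.87
male,169,15.922
male,170,16.114
male,171,16.438
male,174,16.61
male,175,16.62
male,176,16.678
male,177,16.834
male,178,16.946
male,179,16.964
male,180,17.112
male,181,17.302
male,183,17.406
male,184,17.49
male,185,17.56
male,186,17.684
male,187,17.83
male,190,18
female,0,0
female,1,0.178
female,2,0.292
female,3,0.38
female,4,0.486
female,5,0.634
female,6,0.722
female,7,0.77
female,10,0.856
female,11,1
female,12,1.102
female,16,1.154
female,17,1.26
female,18,1.43
female,19,1.66
female,20,1.806
female,21,1.86
female,22,1.998
female,23,2.116
female,24,2.174
female,27,2.272
female,28,2.324
female,32,2.38
female,33,2.524
female,34,2.626
female,35,2.796
female,36,2.988
female,37,3.134
female,38,3.288
female,39,3.382
female,40,3.488
female,45,3.59
female,48,3.644
female,49,3.694
female,50,3.886
female,51,4.084
female,52,4.16
female,53,4.278
female,54,4.518
female,55,4.694
female,56,4.738
female,60,4.814
female,61,4.916
female,62,4.97
female,63,5.02
female,66,5.106
female,67,5.174
female,68,5.322
female,69,5.59
female,70,5.758
female,71,5.81
female,72,5.902
female,76,6.026
female,77,6.228
female,78,6.396
female,79,6.42
female,80,6.448
female,83,6.5
female,84,6.548
female,85,6.656
female,86,6.804
female,87,7.024
female,91,7.192
female,92,7.238
female,93,7.386
female,94,7.516
female,95,7.662
female,96,7.84
female,99,7.928
female,100,7.976
female,101,8.03
female,102,8.098
female,103,8.202
female,104,8.284
female,105,8.342
female,109,8.508
female,110,8.72
female,111,8.868
female,112,9.062
female,113,9.222
female,114,9.27
female,117,9.356
female,118,9.458
female,119,9.56
female,123,9.614
female,124,9.658
female,125,9.76
female,126,9.826
female,127,9.934
female,128,10.184
female,129,10.348
female,130,10.496
female,131,10.674
female,134,10.772
female,135,10.824
female,139,10.88
female,140,10.994
female,141,11.084
female,142,11.138
female,143,11.27
female,144,11.416
female,145,11.488
female,146,11.634
female,147,11.828
female,148,11.976
female,153,12.09
female,156,12.188
female,157,12.386
female,158,12.568
female,159,12.618
female,160,12.672
female,161,12.79
female,162,12.896
female,163,13.044
female,164,13.194
female,165,13.238
female,169,13.356
female,171,13.508
female,174,13.606
female,175,13.802
female,176,14.048
female,177,14.2
female,178,14.27
female,179,14.31
female,180,14.4
female,181,14.468
female,185,14.526
female,186,14.728
female,187,14.898
female,188,14.948
female,191,14.988
female,192,15.036
female,193,15.218
female,194,15.524
female,198,15.688
female,199,15.698
female,200,15.75
female,201,15.898
female,202,16.006
female,203,16.024
female,204,16.162
female,205,16.34
female,208,16.438
female,209,16.518
female,210,16.586
female,211,16.702
female,212,16.84
female,216,17
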