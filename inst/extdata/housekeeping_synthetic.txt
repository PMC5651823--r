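# synthetic housekeeping gene list (one id per line)
g00008
g00009
g00017
g00023
g00045
g00053
g00078
g00079
g00127
g00130
g00143
g00144
g00151
g00166
g00182
g00196
g00204
g00221
g00226
g00231
g00238
g00241
g00273
g00289
g00297
g00301
g00304
g00328
g00333
g00348
g00349
g00350
g00358
g00369
g00371
g00375
g00376
g00378
g00381
g00389
g00390
g00392
g00404
g00416
g00419
g00427
g00429
g00434
g00446
g00447
g00452
g00456
g00463
g00464
g00466
g00472
g00473
g00480
g00484
g00502
g00513
g00515
g00525
g00540
g00548
g00549
g00550
g00556
g00566
g00575
g00587
g00592
g00608
g00614
g00618
g00622
g00624
g00641
g00643
g00646
g00648
g00661
g00665
g00668
g00676
g00683
g00687
g00690
g00697
g00701
g00704
g00710
g00717
g00720
g00736
g00756
g00769
g00774
g00781
g00792
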