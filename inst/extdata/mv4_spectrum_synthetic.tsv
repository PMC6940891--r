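# synthetic 4 MV linac photon spectrum (after collimator)
# shape: truncated gamma continuum w(E) ~ E^0.6 exp(-E/theta),
# theta = 888.6641 keV solved so that the mean energy is 1300 keV
# energy_keV weight
50 0.010978348
100 0.015729675
150 0.018964407
200 0.0213043
250 0.023023855
300 0.02428016
350 0.025175863
400 0.025783644
450 0.02615776
500 0.026340245
550 0.026364538
600 0.026257784
650 0.026042345
700 0.025736865
750 0.025357027
800 0.024916115
850 0.024425443
900 0.023894687
950 0.02333215
1000 0.022744969
1050 0.02213929
1100 0.021520407
1150 0.020892881
1200 0.020260638
1250 0.019627055
1300 0.018995026
1350 0.018367029
1400 0.017745172
1450 0.017131246
1500 0.016526758
1550 0.015932968
1600 0.01535092
1650 0.014781467
1700 0.014225295
1750 0.013682943
1800 0.013154821
1850 0.012641227
1900 0.01214236
1950 0.011658333
2000 0.011189185
2050 0.010734888
2100 0.01029536
2150 0.0098704693
2200 0.0094600426
2250 0.0090638717
2300 0.0086817184
2350 0.0083133194
2400 0.0079583906
2450 0.0076166309
2500 0.0072877257
2550 0.0069713499
2600 0.0066671701
2650 0.0063748476
2700 0.0060940399
2750 0.0058244029
2800 0.005565592
2850 0.0053172639
2900 0.0050790777
2950 0.0048506956
3000 0.0046317842
3050 0.0044220152
3100 0.0042210655
3150 0.0040286187
3200 0.0038443647
3250 0.0036680003
3300 0.0034992298
3350 0.0033377649
3400 0.0031833249
3450 0.0030356369
3500 0.002894436
3550 0.002759465
3600 0.0026304747
3650 0.0025072238
3700 0.0023894788
3750 0.0022770138
3800 0.0021696107
3850 0.0020670589
3900 0.0019691551
3950 0.0018757034
4000 0.001786515
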