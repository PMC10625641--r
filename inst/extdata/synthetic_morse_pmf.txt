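# pmf_table temperature_K=300
# SYNTHETIC potential-of-mean-force table: 2e5 stacking distances drawn by
# rejection sampling from the Morse stacking potential with eps=42.79 pNnm,
# a=2.668 1/nm, r0=0.3742 nm at 300 K (not molecular-dynamics data).
# r_nm pmf_pNnm g count
0.125 37.8146063468507 5e-04 1
0.135 34.943628459904 0.000999999999999999 2
0.145 27.8826546683385 0.00550000000000001 11
0.155 27.1907257440881 0.00649999999999999 13
0.165 24.6512803948001 0.012 24
0.175 21.4487699701945 0.0260000000000001 52
0.185 18.3454725658897 0.055 110
0.195 15.8486061295892 0.1005 201
0.205 13.7825479033633 0.1655 331
0.215 12.0246304353183 0.253 506
0.225 10.2856186638511 0.385000000000001 770
0.235 8.56339307163229 0.583499999999999 1167
0.245 7.17938821642118 0.815000000000002 1630
0.255 6.03831740428771 1.0735 2147
0.265 4.97707307082993 1.387 2774
0.275 3.99293717814154 1.759 3518
0.285 3.05599274769484 2.2055 4411
0.295 2.32925070452879 2.6285 5257
0.305 1.83379049245893 2.9625 5925
0.315 1.28464482820021 3.3825 6765
0.325 0.863520732479747 3.7445 7489
0.335 0.513184000919077 4.07500000000002 8150
0.345 0.327344069835355 4.262 8524
0.355 0.193004092761553 4.4025 8805
0.365 0.0483228699609928 4.559 9118
0.375 0 4.6125 9225
0.385 0.0483228699609928 4.559 9118
0.395 0.177041009180507 4.41950000000002 8839
0.405 0.327830014056009 4.2615 8523
0.415 0.495940661573814 4.092 8184
0.425 0.817321418419632 3.7865 7573
0.435 0.999574064385895 3.6235 7247
0.445 1.31660539175507 3.3565 6713
0.455 1.66462412684989 3.086 6172
0.465 1.96806650137553 2.868 5736
0.475 2.41442487429875 2.575 5150
0.485 2.92111819684916 2.27850000000001 4557
0.495 3.2012384776584 2.12950000000001 4259
0.505 3.76502975087248 1.8585 3717
0.515 4.30206251894459 1.6325 3265
0.525 4.83615700893734 1.435 2870
0.535 5.16961424252295 1.324 2648
0.545 5.76762767654314 1.146 2292
0.555 6.34244998165037 0.997499999999999 1995
0.565 6.82407709205208 0.887999999999999 1776
0.575 7.46606055890478 0.760499999999999 1521
0.585 7.84805095777671 0.693499999999999 1387
0.595 8.718892484605 0.561999999999999 1124
0.605 9.01678280736195 0.523 1046
0.615 9.54842212443488 0.46 920
0.625 10.5009047964359 0.3655 731
0.635 10.9809720988878 0.3255 651
0.645 11.0775253185057 0.318 636
0.655 11.7323223583158 0.2715 543
0.665 12.3479853877739 0.234 468
0.675 13.0086541971524 0.199500000000002 399
0.685 13.377552698724 0.1825 365
0.695 14.1898498507427 0.15 300
0.705 15.0797251028796 0.121 242
0.715 15.3447587087217 0.1135 227
0.725 15.2724084750896 0.1155 231
0.735 16.214626339937 0.0919999999999999 184
0.745 16.4699531076353 0.0864999999999999 173
0.755 17.2587740655759 0.0714999999999999 143
0.765 18.5777920832477 0.052 104
0.775 17.5590464883628 0.0664999999999999 133
0.785 19.8228007662999 0.0385 77
0.795 19.9318056246362 0.0375 75
0.805 19.8769446165078 0.038 76
0.815 20.4612844901814 0.033 66
0.825 20.0437569142261 0.0365 73
0.835 21.2164504528365 0.0275 55
0.845 21.7803025078532 0.0240000000000002 48
0.855 21.7803025078533 0.024 48
0.865 22.6403334528778 0.0195 39
0.875 24.3197478571413 0.013 26
0.885 24.1634294732198 0.0135 27
0.895 25.0116767813918 0.011 22
0.905 24.4821979158466 0.0125 25
0.915 25.0116767813918 0.011 22
0.925 25.0116767813918 0.011 22
0.935 27.5222582817469 0.00599999999999999 12
0.945 27.1907257440881 0.00649999999999999 13
0.955 26.5980098401383 0.00749999999999999 15
0.965 28.2774242444019 0.005 10
0.975 27.8826546683385 0.0055 11
0.985 26.8837745578654 0.00699999999999999 14
0.995 27.8826546683385 0.00550000000000012 11
1.005 27.522258281747 0.00599999999999986 12
1.015 27.8826546683385 0.00550000000000012 11
1.025 28.277424244402 0.00499999999999988 10
1.035 26.8837745578653 0.00700000000000015 14
1.045 29.2016726860105 0.00399999999999991 8
1.055 33.2642140556403 0.00150000000000003 3
1.065 34.943628459904 0.000999999999999977 2
1.075 27.8826546683385 0.00550000000000012 11
1.085 30.3932361686937 0.00299999999999993 6
1.095 32.0726505729571 0.00200000000000004 4
1.105 29.2016726860105 0.00399999999999991 8
1.115 30.3932361686936 0.00300000000000006 6
1.125 33.2642140556405 0.00149999999999997 3
1.135 33.2642140556403 0.00150000000000003 3
1.145 37.8146063468508 0.000499999999999988 1
1.155 31.1484021313486 0.00250000000000005 5
1.175 33.2642140556403 0.00150000000000003 3
1.185 34.943628459904 0.000999999999999977 2
1.195 37.8146063468507 0.000500000000000011 1
1.215 34.9436284599039 0.00100000000000002 2
1.225 34.943628459904 0.000999999999999977 2
1.235 37.8146063468507 0.000500000000000011 1
1.245 34.9436284599039 0.00100000000000002 2
1.255 37.8146063468508 0.000499999999999988 1
1.265 37.8146063468507 0.000500000000000011 1
1.275 34.943628459904 0.000999999999999977 2
1.295 37.8146063468507 5e-04 1
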