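gene_id	length
og1_s1	747
og1_s2	832
og1_s3	910
og1_s4	950
og1_s5	904
og1_s6	908
og1_s7	674
og1_s8	1179
og1_s9	555
og1_s10	722
og1_s11	723
og1_s12	682
og1_s13	891
og1_s14	294
og1_s15	854
og1_s16	925
og1_s17	637
og1_s18	949
og1_s19	889
og1_s20	815
og2_s1	945
og2_s2	452
og2_s3	990
og2_s4	1137
og2_s5	861
og2_s6	631
og2_s7	795
og2_s8	1212
og2_s9	854
og2_s10	934
og2_s11	643
og2_s11.d1	280
og2_s12	961
og2_s13	1146
og2_s14	1130
og2_s15	801
og2_s16	747
og2_s17	789
og2_s18	802
og2_s19	1271
og2_s20	1041
og3_s1	830
og3_s2	729
og3_s3	1117
og3_s4	627
og3_s5	1049
og3_s6	953
og3_s7	949
og3_s8	912
og3_s9	1055
og3_s10	1249
og3_s11	725
og3_s12	1256
og3_s13	827
og3_s14	927
og3_s15	400
og3_s16	172
og3_s17	947
og3_s18	732
og3_s19	658
og3_s20	871
og4_s1	1079
og4_s2	705
og4_s3	701
og4_s4	587
og4_s5	748
og4_s6	1016
og4_s7	1056
og4_s8	696
og4_s9	557
og4_s10	635
og4_s11	1016
og4_s12	783
og4_s13	1265
og4_s14	1065
og4_s15	680
og4_s16	819
og4_s17	792
og4_s18	678
og4_s19	954
og4_s20	651
og5_s1	1022
og5_s2	680
og5_s3	882
og5_s4	997
og5_s5	663
og5_s6	1303
og5_s7	1014
og5_s8	881
og5_s9	850
og5_s10	969
og5_s11	1107
og5_s12	664
og5_s13	757
og5_s14	967
og5_s15	656
og5_s16	883
og5_s17	1149
og5_s18	1142
og5_s19	934
og5_s20	989
og6_s1	1033
og6_s2	681
og6_s3	1170
og6_s4	780
og6_s5	623
og6_s6	824
og6_s7	914
og6_s8	733
og6_s9	532
og6_s10	1027
og6_s11	960
og6_s12	1248
og6_s13	1121
og6_s14	732
og6_s15	977
og6_s16	674
og6_s17	580
og6_s16.d1	541
og6_s17.d1	300
og6_s18	657
og6_s19	821
og6_s20	997
og7_s1	989
og7_s2	607
og7_s3	759
og7_s4	747
og7_s5	1108
og7_s6	1055
og7_s7	1161
og7_s8	691
og7_s9	764
og7_s10	956
og7_s11	889
og7_s12	760
og7_s13	1291
og7_s11.d1	383
og7_s12.d1	335
og7_s13.d1	848
og7_s14	759
og7_s15	521
og7_s16	890
og7_s17	594
og7_s18	596
og7_s19	1089
og7_s20	1072
og8_s1	861
og8_s2	870
og8_s3	1118
og8_s3.d1	472
og8_s4	1024
og8_s5	1032
og8_s6	1322
og8_s7	1089
og8_s8	820
og8_s9	808
og8_s10	1225
og8_s11	1083
og8_s12	664
og8_s13	986
og8_s14	1209
og8_s15	782
og8_s16	955
og8_s17	628
og8_s18	1033
og8_s19	774
og8_s20	550
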