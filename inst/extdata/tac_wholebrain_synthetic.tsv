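mid_s	value
7.5	0.274640334597453
22.5	0.920943876965393
37.5	1.71027755904879
52.5	2.6391806175936
67.5	3.7043113208573
82.5	4.90244287456965
97.5	6.23045946870616
112.5	7.68535246023115
127.5	8.82784898434672
142.5	9.5234634365169
157.5	10.147797766868
172.5	10.7081648663856
187.5	11.211103508665
202.5	11.6624618196586
217.5	12.0674716784195
232.5	12.4308150369066
255	12.9027558816911
285	13.4278328011381
315	13.8486252853654
345	14.1846302179849
390	14.5568029828059
450	14.8896362110888
510	15.0831367505988
570	15.1823188245344
675	15.206972314727
825	15.093366201899
975	14.9018425960166
1125	14.6955913730442
1350	14.4210943380346
1650	14.1554106357573
1950	14.013426646723
2250	13.9731377680934
2550	14.0066486761957
2850	14.0893920034877
3150	14.2024150615945
3450	14.3321008878886
3750	14.469120496659
4050	14.6073246602109
4350	14.7428133092964
4650	14.8732276530389
4950	14.997240054803
5250	15.1141985685179
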