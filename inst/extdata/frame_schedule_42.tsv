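start_s	dur_s
0	15
15	15
30	15
45	15
60	15
75	15
90	15
105	15
120	15
135	15
150	15
165	15
180	15
195	15
210	15
225	15
240	30
270	30
300	30
330	30
360	60
420	60
480	60
540	60
600	150
750	150
900	150
1050	150
1200	300
1500	300
1800	300
2100	300
2400	300
2700	300
3000	300
3300	300
3600	300
3900	300
4200	300
4500	300
4800	300
5100	300
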