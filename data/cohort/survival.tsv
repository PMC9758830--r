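patient_id	time	event
P01	1.59056700907506	1
P02	44.0654698682001	0
P03	34.8348019105552	0
P04	1.90750129121011	1
P05	12.9543449815604	0
P06	9.23073227710619	1
P07	13.5860688125736	0
P08	12.2254813111715	0
P09	74.4253974554357	0
P10	0.0625860760420222	0
P11	14.7148719298872	1
P12	21.7644943324693	1
P13	22.1601967862371	1
P14	5.76315038308363	0
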