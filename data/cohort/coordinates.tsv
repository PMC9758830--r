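sample_id	x_cm	y_cm
P01_R1	-0.509334892336539	-0.415601128822139
P01_R2	1.59771041124726	-1.64667060757986
P01_R3	2.54432071830566	0.476297729177306
P01_R4	-1.98177339302843	0.124781401405589
P01_R5	-0.776817069629663	-2.72348285220171
P02_R1	-1.54736757095222	-2.38072609730207
P02_R2	-1.1520564812651	-1.59715218053958
P02_R3	1.85186568451183	-1.96800973422072
P02_R4	0.0390401462918002	1.63431705734284
P02_R5	0.642929426860146	-1.55687284342709
P02_R6	-0.461307138202783	-2.19137076418705
P02_R7	-2.64343828111845	-0.971096009137296
P03_R1	0.626009024177977	-1.56607336266059
P03_R2	-1.08025954737596	-2.30268111735769
P03_R3	1.2259184155628	-0.127867135482436
P03_R4	-0.345233181995885	1.25273805183896
P03_R5	1.73534878448335	2.15861601055189
P03_R6	-1.7194371092737	-0.781323178000394
P03_R7	1.32267311722656	-1.13088071467245
P03_R8	0.0599189292457621	-0.424681131452543
P03_R9	-1.11404505534156	0.0917181793945033
P04_R1	-0.867675467388297	0.744905668683075
P04_R2	-2.05295200699872	1.94310085355725
P04_R3	-1.89300519814036	-0.0638283068731575
P04_R4	0.868820653097112	-2.78214593982832
P04_R5	0.0167586472000264	1.61503855774579
P04_R6	0.419818202407604	0.353817692942551
P05_R1	-0.64531129325187	-1.24587090341461
P05_R2	-1.4296294723474	1.00828522603456
P05_R3	0.0951458469755085	-0.722668058111366
P05_R4	-2.71194323662611	0.119612516798558
P05_R5	-0.675660233143553	-0.551325668443948
P05_R6	0.821138612511506	-0.335932606585651
P06_R1	-1.08478463587441	-1.74295478323391
P06_R2	-2.6419301280823	0.444593332230539
P06_R3	0.201284556280494	1.49435915355657
P06_R4	0.882516712485701	-1.8862591826438
P06_R5	-1.9797783189162	-0.675312199907689
P06_R6	-2.84255305460161	-0.415348738204237
P06_R7	0.234339678174945	-0.80279645205083
P07_R1	-0.631271400609273	2.79163701922478
P07_R2	-0.445930127177588	-1.73922201433203
P07_R3	-0.12859980910531	-0.594064500519004
P07_R4	-0.119279564533311	2.96165737817184
P07_R5	-0.671018783228355	-0.758042018941123
P08_R1	0.315802903765087	1.79621382110126
P08_R2	0.180318559213416	0.840348900649929
P08_R3	-2.37860169335741	-1.43632373661147
P08_R4	1.972637980038	0.932487947418727
P08_R5	-0.153007868738518	2.83764828689248
P08_R6	-1.56881795615043	0.470414795462206
P09_R1	-0.892075105854838	1.90099954378223
P09_R2	-0.49947854022495	-2.03962552965808
P09_R3	1.63637805406442	1.01194957961633
P09_R4	-1.73780600829991	-0.562229310953137
P09_R5	2.40622154255285	-1.70842793980832
P09_R6	0.541302167007059	-0.0253541431539277
P10_R1	-0.807621330253029	2.10771746011359
P10_R2	-1.5465550244772	2.01304671726651
P10_R3	-2.6761551488653	0.0515597625104836
P10_R4	1.14623114983192	1.28311659620849
P10_R5	1.23060986647967	-1.62599537979043
P10_R6	0.187717440458524	-2.55669736378305
P10_R7	-0.621928888632081	-2.01876743538007
P11_R1	1.14597939363425	0.734668961567568
P11_R2	1.44388756135121	2.4708491032466
P11_R3	-0.351225308487428	1.66736749074612
P11_R4	0.0858144729104066	-0.655887142495024
P11_R5	0.261064505483097	1.01610454925073
P11_R6	-0.668006958976387	-1.44567112774236
P12_R1	-0.60370707833878	-0.041088719968014
P12_R2	0.0221243004170839	-0.416439215541873
P12_R3	-1.86003291794878	1.02303113676229
P12_R4	-2.40689729628914	-1.53644909859052
P12_R5	-0.129883862095115	0.914092327559698
P13_R1	-2.9725038616497	0.0415415117060546
P13_R2	-0.449935152831469	-1.73712453351154
P13_R3	2.29698606050021	1.62078929583539
P13_R4	0.174152992445287	2.83537927813054
P13_R5	-1.90427718105857	-0.171093728067175
P13_R6	-0.699561031660341	-0.463725802025337
P13_R7	1.20455931129656	-0.356653518458097
P13_R8	-1.5036661445376	-0.557410714342632
P13_R9	1.66055291853436	-1.6481240857613
P13_R10	2.79045278685783	-0.685038590459411
P14_R1	-1.38672881444106	1.82217586846211
P14_R2	1.29978954222338	-0.741958502781158
P14_R3	2.11462866843704	0.694272203863001
P14_R4	0.995101294466632	-1.6567170051137
P14_R5	-0.166731995142938	-1.96026105415194
P14_R6	1.47772584957381	1.87509164476644
P14_R7	-0.0380977287335244	-0.610254450288498
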