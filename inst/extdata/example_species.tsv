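species	WDLPS_1	WDLPS_2	WDLPS_3	DDLPS_1	DDLPS_2	DDLPS_3
DG(16:0/14:0)	12663.4	5606.9	4461	5309.8	3412.6	4740.1
DG(16:1/14:0)	14142.9	14255	6562.6	4699	4838.2	4204.7
TG(16:0e/6:0/10:1)	12016.2	12967.1	10671.8	3471	5224.6	7314.6
TG(20:1/18:1/18:3)	13933.9	18297.4	11918	2612.4	5005.4	4074.7
DG(30:3e)	9962.5	15842.5	12029.6	3967	2930.8	5430.4
TG(16:1/14:0/18:2)	12191.6	11302.5	13249.6	3291.8	4646.2	4001.5
TG(16:0/16:1/18:3)	8088.7	10038.5	12244	4819.9	2904.9	4334.3
DG(38:2e)	14201.7	12709.3	5762.3	3086.4	4344.1	8894.8
PC(34:2e)	3520.4	5152.6	3648.1	8485.5	15762.6	18680.2
PC(32:0e)	2391.1	5443	2147.7	10826.3	20609.6	7836.6
Hex1Cer(d18:0/20:4)	3003.7	3264.1	2307.6	11047.8	8901.6	11290.9
PC(40:4)	6009.1	2319.4	2329.4	9629.2	12793.8	9907.8
PC(16:1e/20:4)	5595.4	7332.2	2792.5	12891.9	11763	12640.9
PC(18:2e/20:4)	1443	7250.3	2856.3	7331.6	13062.2	15535.4
PC(38:6e)	1156.4	4939.5	8157.9	6645	7313.9	15194.4
LPE(18:1e)	4096.5	3854.2	3840.2	12615.8	16790.3	6144
PC(14:1e/20:4)	3476.9	4320.1	2126.2	11756.5	18936.5	9406.3
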