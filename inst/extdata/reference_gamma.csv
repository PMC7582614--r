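feature,gamma
hr,0.01281
t1,NA
t2,0.01653
t3,0.01637
t4,0.01604
t5,0.01634
t6,0.01628
t7,0.01673
t8,0.01628
AS,0.01276
dAS,0.01455
sdAS,0.01405
DS,0.01405
dDS,0.01646
sdDS,0.01298
S1,0.01556
S2,0.01411
AA,0.01381
dAA,0.01255
sdAA,0.01298
DA,0.01232
dDA,0.01228
sdDA,0.01265
RAAD,NA
dRAAD,NA
sdRAAD,NA
PI,0.01261
dPI,0.01313
sdPI,0.01305
dVI,0.01296
sdVI,0.01299
AID,0.01324
dAID,0.01311
sdAID,0.01305
dDID,0.01322
sdDID,0.01310
PIR,NA
dPIR,NA
sdPIR,NA
dRIPV,0.01305
sdRIPV,0.01350
AT,0.01348
dAT,0.01634
sdAT,0.01673
DT,0.01490
dDT,0.01628
sdDT,0.01628
dTVO,0.01569
sdTVO,0.01438
Slope_a,0.01308
S3,0.01333
S4,0.01323
RtArea,NA
NI,0.01230
AI,0.01277
AI1,0.01274
RSD,0.01405
RSC,0.01286
RDC,0.01611
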