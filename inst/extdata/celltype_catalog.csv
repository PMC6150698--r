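type_name,description,curated_arbors
P-F3N2d,PBG2-9.s-FBl3.b-NO2D.b,
P-F1N3,PBG2-9.s-FBl1.b-NO3PM.b,
E-PG,PBG1-8.b-EBw.s-DV_GA.b,
P-EG,PBG1-8.s-EBt.b-DV_GA.b,
P-F3N2v,PBG2-9.s-FBl3.b-NO2V.b,
P-EN1,PBG2-9.s-EBt.b-NO1.b.Type1,
P-EN2,PBG2-9.s-EBt.b-NO1.b.Type2,
PF-LCre,PBG1-7.s-FBl2.s-LAL.b-cre.b,
Delta7,PB18.s-GxΔ7Gy.b-PB18.s-9i1i8c.b,PB18.s-PB18.b
IS-P,PBG2-9.b-IB.s.SPS.s,PBG2-9.b-IB.s-SPS.s
IMPL-F,LAL.s-IMP-FBl3.b,
L-Ei,EBIRP I-O-LAL.s,EB.b-LAL.s
L-Em,EBMRP I-O-LAL.s,EB.b-LAL.s
GB-Eo,EBORP O-I-GA-Bulb,EB.b-GA.s-BU.s
AMPG-E,EB.w-AMP.d-D_GAsurround,EBw.b-AMP.s-GA.s
EFBG,EBMRA-FB-LT-LT-GA-GA,EB.b-FB.s-LT.s-GA.s
SMPL-L,SMP.s-LAL.s-LAL.b.contra,
SMPL-L2,SMP.s-LAL.s-LAL.b.contra2,
WL-L,Wedge-LAL.s-LAL.b.contra,
L-Cre,LAL-Cre,
S-P,SPS.s-PB.b,
GL-N1,LAL.s-GAi.s-NO1i.b,
CreL-N2,Cre.s-LAL.s-NO2.b,
L-N3,LAL.s-NO3Ai.b,
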