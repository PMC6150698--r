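"pair_id","pre","post","strength","sign","reliability","significant","control","p_value"
"pair01","PBG1-8.b-EBw.s","PBG2-9.s-FBl3.b",1432.88946090508,1,0.984752089641519,TRUE,FALSE,0.000249937515621095
"pair02","FBl2.b-LAL.s","FBl2.s-NO2D.b",1376.20400324997,1,0.965456389387665,TRUE,FALSE,0.000249937515621095
"pair03","EBt.b-GA.s","EBw.s-PB18.b",1407.05422548325,1,0.971832549089461,TRUE,FALSE,0.000249937515621095
"pair04","NO1.b-LAL.s","NO1.s-SMP.b",1413.52419233505,1,0.980341690535601,TRUE,FALSE,0.000249937515621095
"pair05","FBl5.b-SPS.s","FBl5.s-IB.b",1166.77448597167,-1,0.954995118869631,TRUE,FALSE,0.000249937515621095
"pair06","GA.b-LAL.s","GA.s-Cre.b",1165.48084098328,-1,0.954351466878748,TRUE,FALSE,0.000249937515621095
"pair07","LAL.b-SMP.s","LAL.s-WED.b",3.13103090472256,-1,0.00770165736298231,FALSE,FALSE,0.421394651337166
"pair08","SMP.b-FBl1.s","SMP.s-BU.b",2.26906779208246,-1,-0.019722408522954,FALSE,FALSE,0.55711072231942
"pair09","Cre.b-NO2V.s","Cre.s-SPS.b",4.42046354964371,-1,-0.0852930426073175,FALSE,FALSE,0.311922019495126
"pair10","SPS.b-AMP.s","SPS.s-LAL.b",4.46969173428118,1,-0.0918698850613052,FALSE,FALSE,0.311422144463884
"pair11","SMP.b-LAL.s","WED.b-BU.s",2.44576225727748,-1,-0.0427877175617068,FALSE,TRUE,0.54561359660085
"pair12","SMP.b-LAL.s","IB.b-SPS.s",13.0940665218858,-1,-0.0229249296909161,FALSE,TRUE,0.0997250687328168
"pair13","SMP.b-LAL.s","AMP.b-NO3A.s",15.3517374985793,1,0.0463987499151222,FALSE,TRUE,0.0639840039990003
"pair14","SMP.b-LAL.s","Cre.b-FBl7.s",0.0204084214024217,-1,-0.0215295286219923,FALSE,TRUE,0.99550112471882
"pair15","SMP.b-LAL.s","SMP.b-BU.s",3.75005678661756,1,-0.0848994141041505,FALSE,TRUE,0.344913771557111
"pair16","SMP.b-LAL.s","WED.b-SPS.s",1.23850676544946,1,-0.0603840879493513,FALSE,TRUE,0.711072231942015
"pair17","SMP.b-LAL.s","IB.b-NO3A.s",2.3445620847655,1,-0.061669422088844,FALSE,TRUE,0.553111722069483
"pair18","SMP.b-LAL.s","AMP.b-FBl7.s",2.60413186897268,1,0.00374311681947307,FALSE,TRUE,0.528617845538615
"pair19","SMP.b-LAL.s","Cre.b-LAL.s",22.7707706709057,1,0.104561061859448,TRUE,TRUE,0.00249937515621095
"pair20","WED.b-BU.s","IB.b-SPS.s",0.128938433351293,-1,-0.0174712210813611,FALSE,TRUE,0.873531617095726
"pair21","WED.b-BU.s","AMP.b-NO3A.s",1.76355840429495,1,-0.0232657182539122,FALSE,TRUE,0.616845788552862
"pair22","WED.b-BU.s","Cre.b-FBl7.s",2.56979485044966,-1,0.00868694206030185,FALSE,TRUE,0.534866283429143
"pair23","WED.b-BU.s","SMP.b-BU.s",4.67939848331162,-1,0.0380670884945684,FALSE,TRUE,0.309172706823294
"pair24","WED.b-BU.s","WED.b-SPS.s",0.5041429454283,-1,-0.00154599498642123,FALSE,TRUE,0.761309672581855
"pair25","WED.b-BU.s","IB.b-NO3A.s",1.5367240455697,-1,-0.0512069809808838,FALSE,TRUE,0.648087978005499
"pair26","WED.b-BU.s","AMP.b-FBl7.s",0.179408001855451,-1,-0.0246198705397468,FALSE,TRUE,0.841789552611847
"pair27","WED.b-BU.s","Cre.b-LAL.s",2.28263009605704,1,-0.0329631795255448,FALSE,TRUE,0.55711072231942
"pair28","IB.b-SPS.s","AMP.b-NO3A.s",0.22931380665212,-1,-0.0201102186785592,FALSE,TRUE,0.816545863534117
"pair29","IB.b-SPS.s","Cre.b-FBl7.s",17.7174053396242,-1,0.110964735832817,FALSE,TRUE,0.0334916270932267
"pair30","IB.b-SPS.s","SMP.b-BU.s",3.72266274854476,-1,0.0438562840039596,FALSE,TRUE,0.344913771557111
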