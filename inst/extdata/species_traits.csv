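code,scientific_name,english_name,game,mass_kg,recorded
Tapi.te,Tapirus terrestris,Lowland tapir,TRUE,160,TRUE
Pant.on,Panthera onca,Jaguar,TRUE,80,FALSE
Puma.co,Puma concolor,Puma,TRUE,45,FALSE
Taya.pe,Tayassu pecari,White lipped peccary,TRUE,32,FALSE
Maza.am,Mazama americana,Red brocket deer,TRUE,30,TRUE
Prio.ma,Priodontes maximus,Giant armadillo,TRUE,30,FALSE
Dico.ta,Dicotyles tajacu,Collared peccary,TRUE,25,TRUE
Maza.ne,Mazama nemorivaga,Gray brocket deer,TRUE,18,TRUE
Leop.pa,Leopardus pardalis,Ocelot,TRUE,15,TRUE
Cuni.pa,Cuniculus paca,Paca,TRUE,9.5,TRUE
Puma.ja,Puma yagouaroundi,Jaguarundi,TRUE,8,FALSE
Leop.wi,Leopardus wiedii,Margay,TRUE,6,TRUE
Nasu.na,Nasua nasua,South American coati,TRUE,5.1,TRUE
Dasy.fu,Dasyprocta fuliginosa,Agouti,TRUE,4.5,TRUE
Dasypus,Nonspecific small Cingulata,Armadillos,TRUE,6,TRUE
Hadro.sp,Hadrosciurus spadiceus,Southern Amazon red squirrel,TRUE,1.2,TRUE
Myrm.tr,Myrmecophaga tridactyla,Giant anteater,FALSE,30.5,TRUE
Atel.mi,Atelocynus microtis,Short-eared dog,FALSE,7.75,TRUE
Speo.ve,Speothos venaticus,Bush dog,FALSE,6,FALSE
Proc.ca,Procyon cancrivorus,Crab-eating raccoon,FALSE,5.4,FALSE
Eira.ba,Eira barbara,Tayra,FALSE,4.85,TRUE
Tama.te,Tamandua tetradactyla,Southern tamandua,FALSE,4.5,TRUE
Dide.ma,Didelphis marsupialis,Common opossum,FALSE,1.09,TRUE
Myop.pr,Myoprocta pratti,Acouchi,FALSE,0.75,TRUE
Mitu.tu,Mitu tuberosum,Curassow,TRUE,3,FALSE
Pene.ja,Penelope jacquacu,Spix's guan,TRUE,1.2,TRUE
Psop.le,Psophia leucoptera,Trumpeters,TRUE,1.28,TRUE
Tina.sp,Tinamus spp.,Large tinamou,TRUE,1.2,TRUE
Cryp.sp,Crypturellus spp.,Small tinamou,TRUE,0.42,TRUE
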