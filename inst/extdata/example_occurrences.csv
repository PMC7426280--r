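species,site,sample,life_stage,count,status,trophic,order,method,period
emblyna_sp,GARDEN1,g1_s01,adult,12,endemic,predator,Araneae,SLAM,m01
emblyna_sp,GARDEN1,g1_s02,adult,20,endemic,predator,Araneae,SLAM,m02
emblyna_sp,GARDEN2,g2_s01,adult,4,endemic,predator,Araneae,SLAM,m01
neoscona_sp,GARDEN1,g1_s01,adult,30,introduced,predator,Araneae,SLAM,m01
neoscona_sp,GARDEN1,g1_s01,juvenile,110,introduced,predator,Araneae,SLAM,m01
neoscona_sp,GARDEN1,g1_s02,juvenile,147,introduced,predator,Araneae,SLAM,m02
clubiona_sp,GARDEN2,g2_s01,adult,50,native,predator,Araneae,SLAM,m01
clubiona_sp,GARDEN2,g2_s02,adult,95,native,predator,Araneae,AAS,m02
clubiona_sp,GARDEN2,g2_s02,juvenile,147,native,predator,Araneae,AAS,m02
cyphopterum_sp,GARDEN1,g1_s01,adult,95,native,herbivore,Hemiptera,SLAM,m01
cyphopterum_sp,GARDEN1,g1_s02,juvenile,630,native,herbivore,Hemiptera,SLAM,m02
cyphopterum_sp,GARDEN2,g2_s01,adult,120,native,herbivore,Hemiptera,SLAM,m01
cyphopterum_sp,GARDEN2,g2_s02,juvenile,161,native,herbivore,Hemiptera,AAS,m02
oxycarenus_sp,GARDEN2,g2_s01,adult,136,introduced,herbivore,Hemiptera,SLAM,m01
oxycarenus_sp,GARDEN2,g2_s02,adult,107,introduced,herbivore,Hemiptera,AAS,m02
tachyporus_sp,GARDEN1,g1_s01,adult,48,introduced,predator,Coleoptera,SLAM,m01
sericoderus_sp,GARDEN2,g2_s01,adult,263,introduced,predator,Coleoptera,SLAM,m01
scymnus_morph1,GARDEN1,g1_s02,adult,3,introduced,predator,Coleoptera,SLAM,m02
scymnus_morph2,GARDEN1,g1_s02,adult,2,introduced,predator,Coleoptera,SLAM,m02
morphosp_x,GARDEN2,g2_s02,adult,8,undetermined,unknown,Coleoptera,AAS,m02
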