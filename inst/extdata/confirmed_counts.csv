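disorder,label,category,cases,rule_id,target_group,frequency
PAHD,Phenylalanine hydroxylase deficiency,AAMD,16,HPA,2,"1:18,803"
BH4D,Tetrahydrobiopterin deficiency,AAMD,2,HPA,2,"1:150,425"
CIT1,Citrullinemia type I,AAMD,2,CIT_CD,2,"1:150,425"
CD,Citrin deficiency,AAMD,5,CIT_CD,2,"1:60,170"
HMET,Hypermethioninemia,AAMD,2,MET_HCY,2,"1:150,425"
TYR3,Tyrosinemia type III,AAMD,1,TYR23,2,"1:300,849"
IVA,Isovaleric acidemia,OAMD,2,IVA_2MBD,2,"1:150,425"
GA1,Glutaric acidemia type I,OAMD,1,GA1,2,"1:300,849"
PA,Propionic acidemia,OAMD,3,MMA_PA,2,"1:100,283"
MBD2,2-methylbutyryl-CoA dehydrogenase deficiency,OAMD,3,IVA_2MBD,2,"1:100,283"
MCC3,3-methylcrotonyl-CoA carboxylase deficiency,OAMD,3,MCC_HCS,2,"1:100,283"
PCD,Primary carnitine deficiency,FAOD,22,PCD,1,"1:13,675"
SCADD,Short-chain acyl-CoA dehydrogenase deficiency,FAOD,7,SCADD,2,"1:42,978"
VLCADD,Very-long-chain acyl-CoA dehydrogenase deficiency,FAOD,1,VLCADD,2,"1:300,849"
MADD,Multiple acyl-CoA dehydrogenase deficiency,FAOD,1,MADD,1,"1:300,849"
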