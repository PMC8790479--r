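case_id,diagnosis,sex,subset,marker,value
AA01,BH4D,M,sequenced,PHE,444.79
AA02,BH4D,M,sequenced,PHE,245.11
AA03,PAHD,M,sequenced,PHE,105.43
AA04,PAHD,F,sequenced,PHE,132.91
AA05,PAHD,M,sequenced,PHE,218.86
AA06,PAHD,M,sequenced,PHE,745.62
AA07,PAHD,F,sequenced,PHE,562.35
AA08,PAHD,M,sequenced,PHE,502.76
AA09,PAHD,F,sequenced,PHE,159.60
AA10,PAHD,M,sequenced,PHE,135.63
AA11,PAHD,F,sequenced,PHE,264.59
AA12,PAHD,F,sequenced,PHE,160.25
AA13,HMET,F,sequenced,MET,46.97
AA14,HMET,F,sequenced,MET,75.66
AA15,TYR3,M,sequenced,TYR,447.22
AA16,CIT1,F,sequenced,CIT,350.67
AA17,CIT1,M,sequenced,CIT,39.00
AA18,CD,F,sequenced,CIT,186.21
AA19,CD,M,sequenced,CIT,72.41
AA20,CD,M,sequenced,CIT,92.49
AA21,CD,M,sequenced,CIT,40.68
AA22,CD,F,sequenced,CIT,25.83
OA01,MCC3,M,sequenced,C4DC + C5OH,0.83
OA02,MCC3,M,sequenced,C4DC + C5OH,1.13
OA03,MCC3,M,sequenced,C4DC + C5OH,3.5
OA04,MBD2,M,sequenced,C5,0.43
OA05,MBD2,M,sequenced,C5,0.48
OA06,MBD2,M,sequenced,C5,0.83
OA07,PA,M,sequenced,C3,4.28
OA08,GA1,F,sequenced,C5DC + C6OH,2.49
OA09,IVA,F,sequenced,C5,9.12
OA10,IVA,F,sequenced,C5,1.41
FA01,PCD,M,sequenced,C0,5.15
FA02,PCD,M,sequenced,C0,4.36
FA03,PCD,M,sequenced,C0,4.23
FA04,PCD,F,sequenced,C0,2.79
FA05,PCD,F,sequenced,C0,6.13
FA06,PCD,F,sequenced,C0,5.24
FA07,PCD,F,sequenced,C0,5.11
FA08,PCD,M,sequenced,C0,5.19
FA09,PCD,M,sequenced,C0,5.28
FA10,PCD,M,sequenced,C0,7.54
FA11,PCD,M,sequenced,C0,4.39
FA12,PCD,M,sequenced,C0,1.94
FA13,PCD,F,sequenced,C0,2.47
FA14,PCD,F,sequenced,C0,2.97
FA15,PCD,M,sequenced,C0,5.18
FA16,PCD,F,sequenced,C0,4.94
FA17,PCD,F,sequenced,C0,6.72
FA18,PCD,F,sequenced,C0,3.52
FA19,PCD,M,sequenced,C0,4.88
FA20,PCD,M,sequenced,C0,3.08
FA21,PCD,M,sequenced,C0,4.99
FA22,PCD,F,sequenced,C0,3.25
FA23,VLCADD,F,sequenced,C12,0.66
FA23,VLCADD,F,sequenced,C14,2.76
FA23,VLCADD,F,sequenced,C18,2.23
FA24,MADD,M,sequenced,C5,0.45
FA24,MADD,M,sequenced,(C5DC + C6OH)/(C3DC + C4OH),5.0
FA25,SCADD,M,sequenced,C4,1.46
FA26,SCADD,M,sequenced,C4,1.20
FA27,SCADD,M,sequenced,C4,1.41
FA28,SCADD,M,sequenced,C4,1.83
FA29,SCADD,M,sequenced,C4,0.91
FA30,SCADD,M,sequenced,C4,1.75
FA31,SCADD,F,sequenced,C4,1.61
CL01,PAHD,M,clinical,PHE,701.03
CL02,PAHD,M,clinical,PHE,563.53
CL03,PAHD,F,clinical,PHE,498.89
CL04,PAHD,M,clinical,PHE,148.76
CL05,PAHD,M,clinical,PHE,269.3
CL06,PAHD,F,clinical,PHE,172.9
CL07,PA,M,clinical,C3,10.45
CL08,PA,M,clinical,C3,17.89
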