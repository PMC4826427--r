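site,sex,AU,DK,FI,SC,SE,subtotal,total
all_sites,M,504,401,1000,253,1882,4040,9149
all_sites,F,600,641,1408,280,2180,5109,9149
non_sex_specific,M,443,352,832,222,1480,3329,5992
non_sex_specific,F,364,351,680,146,1122,2663,5992
oesophagus,M,9,4,16,9,29,67,97
oesophagus,F,3,1,5,7,14,30,97
stomach,M,12,6,47,5,64,134,254
stomach,F,13,14,50,4,39,120,254
colon,M,NA,26,56,18,173,273,483
colon,F,NA,16,66,9,119,210,483
rectum,M,NA,13,46,15,84,158,272
rectum,F,NA,10,41,6,57,114,272
colorectal,M,61,39,102,33,257,492,876
colorectal,F,60,26,107,15,176,384,876
liver,M,14,9,34,12,44,113,154
liver,F,7,6,8,3,17,41,154
pancreas,M,19,15,54,7,52,147,240
pancreas,F,8,9,41,5,30,93,240
lung,M,41,39,119,37,134,370,642
lung,F,29,38,58,19,128,272,642
melanoma,M,86,21,60,16,122,305,613
melanoma,F,72,59,59,15,103,308,613
breast,F,184,184,546,99,710,1723,1723
cervix,F,11,48,36,14,85,194,194
endometrium,F,25,40,97,12,149,323,323
ovary,F,22,25,80,11,114,252,252
prostate,M,41,12,148,11,341,553,553
testis,M,22,37,23,20,57,159,159
kidney,M,21,23,67,14,62,187,305
kidney,F,15,15,47,4,37,118,305
bladder,M,12,17,49,11,124,213,279
bladder,F,2,7,16,6,35,66,279
brain_cns,M,17,31,35,18,79,180,393
brain_cns,F,13,42,32,28,98,213,393
thyroid,M,15,6,18,4,15,58,299
thyroid,F,45,29,104,12,51,241,299
nhl,M,30,26,56,21,111,244,387
nhl,F,19,14,46,8,56,143,387
hodgkin,M,11,11,14,NA,20,56,80
hodgkin,F,2,4,9,NA,9,24,80
myeloma,M,2,4,14,3,26,53,81
myeloma,F,2,5,8,0,13,28,81
leukaemia,M,NA,14,39,13,38,104,190
leukaemia,F,NA,16,33,9,28,86,190
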