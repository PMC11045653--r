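site_group,row_type,stage,index_n,index_pct,non_index_n,non_index_pct,non_cancer_n,non_cancer_pct
All Types,all_types,I,66737,25,31785,12,170318,63
All Types,all_types,II,85179,26,39125,12,201719,62
All Types,all_types,III,93826,62,9468,6,49183,32
All Types,all_types,IV,171607,85,4279,2,26698,13
All Types,all_types,Unknown,119567,58,11375,6,73651,36
Bladder,parent,I,3060,29,1251,12,6129,59
Bladder,parent,II,2567,53,428,9,1850,38
Bladder,parent,III,1224,59,116,6,725,35
Bladder,parent,IV,2867,82,126,4,518,15
Bladder,parent,Unknown,903,49,115,6,837,45
"Breast, All",parent,I,11259,15,10032,13,54126,72
"Breast, All",parent,II,15448,31,5289,11,28748,58
"Breast, All",parent,III,9788,57,1281,7,6227,36
"Breast, All",parent,IV,7377,87,94,1,1011,12
"Breast, All",parent,Unknown,3733,48,509,6,3597,46
"Breast, HR-positive",subtype,I,8929,14,8618,14,45559,72
"Breast, HR-positive",subtype,II,11783,31,4049,11,21802,58
"Breast, HR-positive",subtype,III,6935,56,911,7,4468,36
"Breast, HR-positive",subtype,IV,4728,86,64,1,706,13
"Breast, HR-positive",subtype,Unknown,1635,42,248,6,2030,52
"Breast, HR-negative",subtype,I,1906,20,1156,12,6422,68
"Breast, HR-negative",subtype,II,2944,30,1153,12,5722,58
"Breast, HR-negative",subtype,III,2284,54,340,8,1626,38
"Breast, HR-negative",subtype,IV,1562,87,21,1,215,12
"Breast, HR-negative",subtype,Unknown,399,40,123,12,479,48
"Breast, HR-unknown",subtype,I,420,16,268,10,2008,74
"Breast, HR-unknown",subtype,II,613,32,126,6,1206,62
"Breast, HR-unknown",subtype,III,435,64,49,7,201,29
"Breast, HR-unknown",subtype,IV,1051,91,11,1,95,8
"Breast, HR-unknown",subtype,Unknown,1646,56,166,6,1102,38
Cervix,parent,I,586,26,284,13,1358,61
Cervix,parent,II,507,48,133,13,420,40
Cervix,parent,III,883,62,120,8,429,30
Cervix,parent,IV,984,84,10,1,173,15
Cervix,parent,Unknown,388,64,51,8,171,28
Colon/Rectum,parent,I,4806,19,2896,11,17869,70
Colon/Rectum,parent,II,7853,31,2332,9,15364,60
Colon/Rectum,parent,III,12134,47,1952,8,11928,46
Colon/Rectum,parent,IV,18555,90,206,1,1755,9
Colon/Rectum,parent,Unknown,4078,44,950,10,4330,46
Esophagus,parent,I,999,54,78,4,784,42
Esophagus,parent,II,1429,71,82,4,500,25
Esophagus,parent,III,1789,81,84,4,328,15
Esophagus,parent,IV,3841,94,22,1,240,6
Esophagus,parent,Unknown,1452,82,33,2,286,16
Kidney,parent,I,4428,23,2518,13,12622,65
Kidney,parent,II,1363,42,279,9,1595,49
Kidney,parent,III,2881,54,352,7,2078,39
Kidney,parent,IV,5901,90,79,1,608,9
Kidney,parent,Unknown,1140,50,214,9,944,41
Larynx,parent,I,1065,33,337,10,1872,57
Larynx,parent,II,659,45,156,11,640,44
Larynx,parent,III,812,56,131,9,505,35
Larynx,parent,IV,1718,68,153,6,673,26
Larynx,parent,Unknown,362,49,51,7,319,44
Liver/Intrahepatic Bile Duct,parent,I,4353,70,345,6,1559,25
Liver/Intrahepatic Bile Duct,parent,II,2462,71,172,5,840,24
Liver/Intrahepatic Bile Duct,parent,III,3958,91,20,0,373,9
Liver/Intrahepatic Bile Duct,parent,IV,3497,92,16,0,272,7
Liver/Intrahepatic Bile Duct,parent,Unknown,4427,87,72,1,577,11
"Lung, All",parent,I,14134,53,1115,4,11476,43
"Lung, All",parent,II,4626,71,158,2,1717,26
"Lung, All",parent,III,30907,84,482,1,5420,15
"Lung, All",parent,IV,65620,93,377,1,4604,7
"Lung, All",parent,Unknown,12182,78,238,2,3145,20
"Lung, Non-Small-Cell",subtype,I,10742,51,953,5,9353,44
"Lung, Non-Small-Cell",subtype,II,3363,70,119,2,1323,28
"Lung, Non-Small-Cell",subtype,III,18255,84,329,2,3123,14
"Lung, Non-Small-Cell",subtype,IV,33160,93,204,1,2166,6
"Lung, Non-Small-Cell",subtype,Unknown,4249,82,54,1,852,17
"Lung, Small-Cell",subtype,I,615,73,13,2,217,26
"Lung, Small-Cell",subtype,II,304,80,6,2,71,19
"Lung, Small-Cell",subtype,III,5091,86,46,1,759,13
"Lung, Small-Cell",subtype,IV,12285,94,34,0,701,5
"Lung, Small-Cell",subtype,Unknown,1191,88,10,1,158,12
Lymphoma,parent,I,4305,34,1334,11,7059,56
Lymphoma,parent,II,2963,40,602,8,3768,51
Lymphoma,parent,III,4020,49,613,7,3574,44
Lymphoma,parent,IV,8958,54,1091,7,6672,40
Lymphoma,parent,Unknown,1732,43,358,9,1924,48
Melanoma,parent,I,3101,11,5151,17,21193,72
Melanoma,parent,II,1706,34,489,10,2856,57
Melanoma,parent,III,1544,59,244,9,843,32
Melanoma,parent,IV,1442,83,33,2,257,15
Melanoma,parent,Unknown,1126,26,450,10,2776,64
Oral Cavity/Pharynx,parent,I,1086,25,671,16,2508,59
Oral Cavity/Pharynx,parent,II,1128,40,249,9,1460,51
Oral Cavity/Pharynx,parent,III,1826,49,339,9,1588,42
Oral Cavity/Pharynx,parent,IV,6736,59,803,7,3801,34
Oral Cavity/Pharynx,parent,Unknown,2201,46,481,10,2100,44
Ovary,parent,I,799,29,368,13,1626,58
Ovary,parent,II,826,69,61,5,307,26
Ovary,parent,III,5170,88,105,2,617,10
Ovary,parent,IV,4333,91,47,1,357,8
Ovary,parent,Unknown,1457,77,64,3,365,19
Pancreas,parent,I,1389,76,57,3,383,21
Pancreas,parent,II,6175,89,55,1,712,10
Pancreas,parent,III,2415,95,7,0,109,4
Pancreas,parent,IV,14634,96,42,0,605,4
Pancreas,parent,Unknown,3858,89,55,1,444,10
Prostate,parent,I,19,10,19,9,164,81
Prostate,parent,II,29688,15,27419,14,134472,70
Prostate,parent,III,5637,34,2521,15,8560,51
Prostate,parent,IV,9236,71,627,5,3169,24
Prostate,parent,Unknown,4540,29,1766,11,9328,60
Stomach,parent,I,1807,46,256,6,1896,48
Stomach,parent,II,1312,70,77,4,491,26
Stomach,parent,III,1456,79,66,4,326,18
Stomach,parent,IV,6241,93,62,1,424,6
Stomach,parent,Unknown,2074,56,253,7,1395,37
Thyroid,parent,I,363,4,1857,19,7488,77
Thyroid,parent,II,192,8,684,29,1516,63
Thyroid,parent,III,593,16,394,11,2668,73
Thyroid,parent,IV,1503,58,304,12,784,30
Thyroid,parent,Unknown,269,18,370,25,851,57
Uterus,parent,I,3407,14,3291,14,17318,72
Uterus,parent,II,591,24,258,10,1607,65
Uterus,parent,III,2394,51,424,9,1836,39
Uterus,parent,IV,2062,85,47,2,306,13
Uterus,parent,Unknown,2265,57,266,7,1417,36
Other Types,parent,I,2872,33,1095,13,4614,54
Other Types,parent,II,3490,52,576,9,2674,40
Other Types,parent,III,3710,66,432,8,1519,27
Other Types,parent,IV,5899,88,173,3,638,10
Other Types,parent,Unknown,70888,61,5323,5,39092,34
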