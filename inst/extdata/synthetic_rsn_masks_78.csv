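"region","DMN","SMN","FPN","VIS"
"region_L_01",0,1,0,0
"region_L_02",0,0,0,0
"region_L_03",0,0,0,0
"region_L_04",0,1,1,0
"region_L_05",0,0,1,0
"region_L_06",1,0,0,0
"region_L_07",1,0,0,0
"region_L_08",0,1,0,0
"region_L_09",0,1,1,0
"region_L_10",1,0,0,0
"region_L_11",1,0,0,1
"region_L_12",0,0,1,0
"region_L_13",0,0,1,0
"region_L_14",0,0,0,0
"region_L_15",1,0,0,0
"region_L_16",0,0,0,0
"region_L_17",0,0,0,0
"region_L_18",0,0,0,0
"region_L_19",0,0,0,1
"region_L_20",0,0,0,0
"region_L_21",0,0,0,0
"region_L_22",0,0,0,0
"region_L_23",1,0,0,0
"region_L_24",0,0,0,1
"region_L_25",0,0,0,0
"region_L_26",0,0,0,0
"region_L_27",0,0,0,1
"region_L_28",0,0,0,0
"region_L_29",0,0,0,0
"region_L_30",0,0,0,0
"region_L_31",0,0,0,0
"region_L_32",0,0,0,0
"region_L_33",0,0,0,0
"region_L_34",0,0,0,0
"region_L_35",0,0,0,0
"region_L_36",0,0,0,0
"region_L_37",0,0,0,0
"region_L_38",0,0,0,0
"region_L_39",0,0,0,0
"region_R_01",0,1,0,0
"region_R_02",0,0,0,0
"region_R_03",0,0,0,0
"region_R_04",0,1,1,0
"region_R_05",0,0,1,0
"region_R_06",1,0,0,0
"region_R_07",1,0,0,0
"region_R_08",0,1,0,0
"region_R_09",0,1,1,0
"region_R_10",1,0,0,0
"region_R_11",1,0,0,1
"region_R_12",0,0,1,0
"region_R_13",0,0,1,0
"region_R_14",0,0,0,0
"region_R_15",1,0,0,0
"region_R_16",0,0,0,0
"region_R_17",0,0,0,0
"region_R_18",0,0,0,0
"region_R_19",0,0,0,1
"region_R_20",0,0,0,0
"region_R_21",0,0,0,0
"region_R_22",0,0,0,0
"region_R_23",1,0,0,0
"region_R_24",0,0,0,1
"region_R_25",0,0,0,0
"region_R_26",0,0,0,0
"region_R_27",0,0,0,1
"region_R_28",0,0,0,0
"region_R_29",0,0,0,0
"region_R_30",0,0,0,0
"region_R_31",0,0,0,0
"region_R_32",0,0,0,0
"region_R_33",0,0,0,0
"region_R_34",0,0,0,0
"region_R_35",0,0,0,0
"region_R_36",0,0,0,0
"region_R_37",0,0,0,0
"region_R_38",0,0,0,0
"region_R_39",0,0,0,0
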