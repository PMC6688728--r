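"region","x_mm","y_mm","z_mm"
"region_L_01",-13.9,-10.6,50.9
"region_L_02",-7.6,26.9,48.8
"region_L_03",-20.4,-27.4,46.6
"region_L_04",-33.2,7.1,44.5
"region_L_05",-32.2,24.5,42.3
"region_L_06",-14.8,-48.2,40.2
"region_L_07",-22.9,47.7,38.1
"region_L_08",-42.6,-19.6,35.9
"region_L_09",-44,-23,33.8
"region_L_10",-24.2,57.1,31.6
"region_L_11",-19.4,-62.6,29.5
"region_L_12",-46.1,34,27.3
"region_L_13",-52.6,15,25.2
"region_L_14",-34.2,-58.8,23
"region_L_15",-12.5,73.1,20.9
"region_L_16",-45.3,-48.5,18.7
"region_L_17",-58.4,-3.2,16.6
"region_L_18",-43.8,55.1,14.4
"region_L_19",-8.5,-79.2,12.3
"region_L_20",-41.1,61.7,10.1
"region_L_21",-61,-10.8,8
"region_L_22",-52,-46.9,5.9
"region_L_23",-18.4,80.9,3.7
"region_L_24",-34.3,-72.5,1.6
"region_L_25",-60.6,25.5,-0.6
"region_L_26",-58.3,35.4,-2.7
"region_L_27",-28.3,-78.1,-4.9
"region_L_28",-25.6,79.9,-7
"region_L_29",-57.3,-39.5,-9.2
"region_L_30",-62.1,-21.7,-11.3
"region_L_31",-37.3,71.4,-13.5
"region_L_32",-15.8,-83.4,-15.6
"region_L_33",-51.5,51.6,-17.8
"region_L_34",-63.1,6.9,-19.9
"region_L_35",-44.6,-61.2,-22
"region_L_36",-6.3,82.7,-24.2
"region_L_37",-43.6,-60.7,-26.3
"region_L_38",-61.1,7.5,-28.5
"region_L_39",-49.6,48.5,-30.6
"region_R_01",13.9,-10.6,50.9
"region_R_02",7.6,26.9,48.8
"region_R_03",20.4,-27.4,46.6
"region_R_04",33.2,7.1,44.5
"region_R_05",32.2,24.5,42.3
"region_R_06",14.8,-48.2,40.2
"region_R_07",22.9,47.7,38.1
"region_R_08",42.6,-19.6,35.9
"region_R_09",44,-23,33.8
"region_R_10",24.2,57.1,31.6
"region_R_11",19.4,-62.6,29.5
"region_R_12",46.1,34,27.3
"region_R_13",52.6,15,25.2
"region_R_14",34.2,-58.8,23
"region_R_15",12.5,73.1,20.9
"region_R_16",45.3,-48.5,18.7
"region_R_17",58.4,-3.2,16.6
"region_R_18",43.8,55.1,14.4
"region_R_19",8.5,-79.2,12.3
"region_R_20",41.1,61.7,10.1
"region_R_21",61,-10.8,8
"region_R_22",52,-46.9,5.9
"region_R_23",18.4,80.9,3.7
"region_R_24",34.3,-72.5,1.6
"region_R_25",60.6,25.5,-0.6
"region_R_26",58.3,35.4,-2.7
"region_R_27",28.3,-78.1,-4.9
"region_R_28",25.6,79.9,-7
"region_R_29",57.3,-39.5,-9.2
"region_R_30",62.1,-21.7,-11.3
"region_R_31",37.3,71.4,-13.5
"region_R_32",15.8,-83.4,-15.6
"region_R_33",51.5,51.6,-17.8
"region_R_34",63.1,6.9,-19.9
"region_R_35",44.6,-61.2,-22
"region_R_36",6.3,82.7,-24.2
"region_R_37",43.6,-60.7,-26.3
"region_R_38",61.1,7.5,-28.5
"region_R_39",49.6,48.5,-30.6
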