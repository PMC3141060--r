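"age","sex","race","expectancy_years"
0,"F","black",73.01
5,"F","black",68.04
10,"F","black",63.09
15,"F","black",58.16
20,"F","black",53.25
25,"F","black",48.39
30,"F","black",43.59
35,"F","black",38.86
40,"F","black",34.24
45,"F","black",29.76
50,"F","black",25.47
55,"F","black",21.41
60,"F","black",17.64
65,"F","black",14.21
70,"F","black",11.17
75,"F","black",8.55
80,"F","black",6.37
85,"F","black",4.62
90,"F","black",3.26
95,"F","black",2.25
100,"F","black",1.52
0,"F","hispanic",76.64
5,"F","hispanic",71.67
10,"F","hispanic",66.7
15,"F","hispanic",61.75
20,"F","hispanic",56.83
25,"F","hispanic",51.93
30,"F","hispanic",47.09
35,"F","hispanic",42.3
40,"F","hispanic",37.6
45,"F","hispanic",33.02
50,"F","hispanic",28.59
55,"F","hispanic",24.35
60,"F","hispanic",20.37
65,"F","hispanic",16.68
70,"F","hispanic",13.35
75,"F","hispanic",10.42
80,"F","hispanic",7.92
85,"F","hispanic",5.86
90,"F","hispanic",4.22
95,"F","hispanic",2.96
100,"F","hispanic",2.03
0,"F","other",75.48
5,"F","other",70.51
10,"F","other",65.54
15,"F","other",60.6
20,"F","other",55.68
25,"F","other",50.79
30,"F","other",45.96
35,"F","other",41.19
40,"F","other",36.52
45,"F","other",31.96
50,"F","other",27.57
55,"F","other",23.39
60,"F","other",19.47
65,"F","other",15.87
70,"F","other",12.63
75,"F","other",9.8
80,"F","other",7.4
85,"F","other",5.44
90,"F","other",3.89
95,"F","other",2.71
100,"F","other",1.85
0,"F","white",75.48
5,"F","white",70.51
10,"F","white",65.54
15,"F","white",60.6
20,"F","white",55.68
25,"F","white",50.79
30,"F","white",45.96
35,"F","white",41.19
40,"F","white",36.52
45,"F","white",31.96
50,"F","white",27.57
55,"F","white",23.39
60,"F","white",19.47
65,"F","white",15.87
70,"F","white",12.63
75,"F","white",9.8
80,"F","white",7.4
85,"F","white",5.44
90,"F","white",3.89
95,"F","white",2.71
100,"F","white",1.85
0,"M","black",68.32
5,"M","black",63.37
10,"M","black",58.43
15,"M","black",53.52
20,"M","black",48.66
25,"M","black",43.85
30,"M","black",39.12
35,"M","black",34.5
40,"M","black",30.01
45,"M","black",25.71
50,"M","black",21.63
55,"M","black",17.85
60,"M","black",14.39
65,"M","black",11.33
70,"M","black",8.69
75,"M","black",6.48
80,"M","black",4.71
85,"M","black",3.33
90,"M","black",2.3
95,"M","black",1.56
100,"M","black",1.04
0,"M","hispanic",71.95
5,"M","hispanic",66.98
10,"M","hispanic",62.03
15,"M","hispanic",57.1
20,"M","hispanic",52.21
25,"M","hispanic",47.36
30,"M","hispanic",42.57
35,"M","hispanic",37.86
40,"M","hispanic",33.27
45,"M","hispanic",28.83
50,"M","hispanic",24.58
55,"M","hispanic",20.58
60,"M","hispanic",16.88
65,"M","hispanic",13.53
70,"M","hispanic",10.57
75,"M","hispanic",8.05
80,"M","hispanic",5.96
85,"M","hispanic",4.3
90,"M","hispanic",3.02
95,"M","hispanic",2.07
100,"M","hispanic",1.4
0,"M","other",70.78
5,"M","other",65.82
10,"M","other",60.87
15,"M","other",55.95
20,"M","other",51.07
25,"M","other",46.23
30,"M","other",41.46
35,"M","other",36.77
40,"M","other",32.21
45,"M","other",27.81
50,"M","other",23.62
55,"M","other",19.68
60,"M","other",16.06
65,"M","other",12.8
70,"M","other",9.94
75,"M","other",7.52
80,"M","other",5.53
85,"M","other",3.96
90,"M","other",2.77
95,"M","other",1.89
100,"M","other",1.27
0,"M","white",70.78
5,"M","white",65.82
10,"M","white",60.87
15,"M","white",55.95
20,"M","white",51.07
25,"M","white",46.23
30,"M","white",41.46
35,"M","white",36.77
40,"M","white",32.21
45,"M","white",27.81
50,"M","white",23.62
55,"M","white",19.68
60,"M","white",16.06
65,"M","white",12.8
70,"M","white",9.94
75,"M","white",7.52
80,"M","white",5.53
85,"M","white",3.96
90,"M","white",2.77
95,"M","white",1.89
100,"M","white",1.27
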