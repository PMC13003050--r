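hospital_id,traffic,season,location_label,occupancy_fraction,concentration,n_staff
HTH,HT,hot,emergency room,0.9,770,2
HTH,HT,hot,intensive care unit,0.9,786,3
HTH,HT,hot,operation room,0.9,802,4
HTH,HT,hot,clinic 1,0.9,818,5
HTH,HT,hot,clinic 2,0.9,834,2
HTH,HT,hot,patient room 1,0.9,850,3
HTH,HT,hot,patient room 2,0.9,866,4
HTH,HT,hot,patient room 3,0.9,882,5
HTH,HT,hot,administrative office 1,0.5,898,2
HTH,HT,hot,administrative office 2,0.5,914,3
HTH,HT,hot,pharmacy 1,0.5,930,4
HTH,HT,cold,emergency room,0.9,500,2
HTH,HT,cold,intensive care unit,0.9,510,3
HTH,HT,cold,operation room,0.9,520,4
HTH,HT,cold,clinic 1,0.9,530,5
HTH,HT,cold,clinic 2,0.9,540,2
HTH,HT,cold,patient room 1,0.9,550,3
HTH,HT,cold,patient room 2,0.9,560,4
HTH,HT,cold,administrative office 1,0.5,570,5
HTH,HT,cold,administrative office 2,0.5,580,2
HTH,HT,cold,pharmacy 1,0.5,590,3
HTH,HT,cold,pharmacy 2,0.5,600,4
MTH,MT,hot,emergency room,0.9,460,2
MTH,MT,hot,intensive care unit,0.9,462.5,3
MTH,MT,hot,operation room,0.9,465,4
MTH,MT,hot,clinic 1,0.9,467.5,5
MTH,MT,hot,clinic 2,0.9,470,2
MTH,MT,hot,patient room 1,0.9,472.5,3
MTH,MT,hot,patient room 2,0.9,475,4
MTH,MT,hot,administrative office 1,0.5,477.5,5
MTH,MT,hot,administrative office 2,0.5,480,2
MTH,MT,cold,emergency room,0.9,360,2
MTH,MT,cold,intensive care unit,0.9,361.25,3
MTH,MT,cold,operation room,0.9,362.5,4
MTH,MT,cold,clinic 1,0.9,363.75,5
MTH,MT,cold,clinic 2,0.9,365,2
MTH,MT,cold,patient room 1,0.9,366.25,3
MTH,MT,cold,patient room 2,0.9,367.5,4
MTH,MT,cold,administrative office 1,0.5,368.75,5
MTH,MT,cold,administrative office 2,0.5,370,2
OSH,OS,hot,emergency room,0.9,270,2
OSH,OS,hot,intensive care unit,0.9,293.33,3
OSH,OS,hot,operation room,0.9,316.67,4
OSH,OS,hot,clinic 1,0.9,340,5
OSH,OS,hot,administrative office 1,0.5,363.33,2
OSH,OS,hot,administrative office 2,0.5,386.67,3
OSH,OS,hot,pharmacy 1,0.5,410,4
OSH,OS,cold,emergency room,0.9,170,2
OSH,OS,cold,intensive care unit,0.9,186.67,3
OSH,OS,cold,operation room,0.9,203.33,4
OSH,OS,cold,clinic 1,0.9,220,5
OSH,OS,cold,administrative office 1,0.5,236.67,2
OSH,OS,cold,administrative office 2,0.5,253.33,3
OSH,OS,cold,pharmacy 1,0.5,270,4
LTH,LT,hot,emergency room,0.9,270,2
LTH,LT,hot,intensive care unit,0.9,276,3
LTH,LT,hot,operation room,0.9,282,4
LTH,LT,hot,clinic 1,0.9,288,5
LTH,LT,hot,clinic 2,0.9,294,2
LTH,LT,hot,patient room 1,0.9,300,3
LTH,LT,hot,administrative office 1,0.5,306,4
LTH,LT,hot,administrative office 2,0.5,312,5
LTH,LT,hot,pharmacy 1,0.5,318,2
LTH,LT,hot,pharmacy 2,0.5,324,3
LTH,LT,hot,laboratory,0.5,330,4
LTH,LT,cold,emergency room,0.9,220,2
LTH,LT,cold,intensive care unit,0.9,225,3
LTH,LT,cold,operation room,0.9,230,4
LTH,LT,cold,clinic 1,0.9,235,5
LTH,LT,cold,clinic 2,0.9,240,2
LTH,LT,cold,patient room 1,0.9,245,3
LTH,LT,cold,administrative office 1,0.5,250,4
LTH,LT,cold,administrative office 2,0.5,255,5
LTH,LT,cold,pharmacy 1,0.5,260,2
LTH,LT,cold,pharmacy 2,0.5,265,3
LTH,LT,cold,laboratory,0.5,270,4
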