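condition,response,temperature_C,time_s,yield_pct,replicate
CE,TPC,5,60,22.1390426844213,1
CE,TPC,5,120,30.6755642802081,1
CE,TPC,5,180,36.4141520646618,1
CE,TPC,5,240,40.6933931488395,1
CE,TPC,5,300,44.055259055415,1
CE,TPC,5,360,46.7833163281231,1
CE,TPC,5,480,50.9574510021467,1
CE,TPC,5,600,54.0002286881354,1
CE,TPC,5,1800,64.4607868007984,1
CE,TPC,15,60,34.184576681043,1
CE,TPC,15,120,44.482071784184,1
CE,TPC,15,180,50.4457924083605,1
CE,TPC,15,240,54.3708913092454,1
CE,TPC,15,300,57.13091301573,1
CE,TPC,15,360,59.1548131308416,1
CE,TPC,15,480,61.8638715282816,1
CE,TPC,15,600,63.5309527654648,1
CE,TPC,15,1800,67.057872570839,1
CE,TPC,25,60,47.2900505501013,1
CE,TPC,25,120,56.7175553990102,1
CE,TPC,25,180,60.9968773788629,1
CE,TPC,25,240,63.2948043784814,1
CE,TPC,25,300,64.6438376519324,1
CE,TPC,25,360,65.4827811755568,1
CE,TPC,25,480,66.38998996905,1
CE,TPC,25,600,66.8135958092786,1
CE,TPC,25,1800,67.2955546003322,1
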