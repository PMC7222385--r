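condition,response,temperature_C,time_s,concentration,c_max
CE,TPC,5,60,370.6076,1674
CE,TPC,5,120,513.5089,1674
CE,TPC,5,180,609.5729,1674
CE,TPC,5,240,681.2074,1674
CE,TPC,5,300,737.485,1674
CE,TPC,5,360,783.1527,1674
CE,TPC,5,480,853.0277,1674
CE,TPC,5,600,903.9638,1674
CE,TPC,5,1800,1079.0736,1674
CE,TPC,15,60,572.2498,1674
CE,TPC,15,120,744.6299,1674
CE,TPC,15,180,844.4626,1674
CE,TPC,15,240,910.1687,1674
CE,TPC,15,300,956.3715,1674
CE,TPC,15,360,990.2516,1674
CE,TPC,15,480,1035.6012,1674
CE,TPC,15,600,1063.5081,1674
CE,TPC,15,1800,1122.5488,1674
CE,TPC,25,60,791.6354,1674
CE,TPC,25,120,949.4519,1674
CE,TPC,25,180,1021.0877,1674
CE,TPC,25,240,1059.555,1674
CE,TPC,25,300,1082.1378,1674
CE,TPC,25,360,1096.1818,1674
CE,TPC,25,480,1111.3684,1674
CE,TPC,25,600,1118.4596,1674
CE,TPC,25,1800,1126.5276,1674
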