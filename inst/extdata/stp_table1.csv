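area,stp,lowest,p1,median,highest,rr,lo,hi,paf,fuel_poverty
England,NA,-7.00,-2.97,5.80,14.30,1.35,1.30,1.40,14.05,11.04
Cambridgeshire and Peterborough,21,-8.53,-3.06,6.09,15.89,1.19,1.01,1.40,8.58,8.14
Lincolnshire,13,-7.13,-2.72,5.58,15.82,1.23,1.04,1.45,10.65,12.22
South Yorkshire and Bassetlaw,9,-6.55,-3.09,5.44,15.85,1.23,1.09,1.39,10.81,11.60
North East London,29,-2.20,-1.03,7.35,16.42,1.25,1.10,1.42,11.24,11.03
Norfolk and Waveney,22,-5.66,-1.47,5.99,15.90,1.26,1.10,1.46,12.52,9.54
Hertfordshire and West Essex,25,-7.08,-3.04,5.60,15.25,1.28,1.13,1.46,12.64,7.08
South West London,31,-3.95,-2.14,6.45,15.30,1.29,1.12,1.47,12.29,9.13
Lancashire and South Cumbria,4,-5.01,-2.54,5.85,14.02,1.30,1.18,1.44,12.66,12.07
"Northumberland, Tyne, and Wear",1,-7.11,-3.31,3.94,13.78,1.30,1.16,1.46,13.99,13.14
"Durham, Darlington, Tees, Hambleton, Richmondshire, and Whitby",3,-8.29,-3.84,4.43,14.21,1.30,1.14,1.48,13.49,13.21
West Yorkshire,5,-6.64,-2.13,5.41,14.55,1.31,1.19,1.44,13.95,13.24
Nottinghamshire,14,-7.30,-2.60,5.75,15.68,1.31,1.13,1.51,13.83,12.84
Kent and Medway,32,-3.51,-1.49,6.76,15.38,1.32,1.18,1.47,13.58,10.05
South East London,30,-3.26,-1.63,7.08,15.65,1.33,1.17,1.50,13.63,8.77
Herefordshire and Worcestershire,19,-8.93,-3.23,5.96,15.03,1.33,1.14,1.56,13.60,13.48
Northamptonshire,20,-5.99,-3.33,5.40,14.98,1.33,1.20,1.48,21.14,11.84
"Milton Keynes, Bedfordshire, and Luton",24,-7.25,-3.07,6.02,15.28,1.34,1.14,1.58,14.20,8.03
"Buckinghamshire, Oxfordshire, and Berkshire West",44,-6.16,-2.94,5.94,14.93,1.34,1.19,1.51,14.12,9.35
"Bath, Swindon and Wiltshire",40,-4.43,-2.36,6.10,14.28,1.34,1.16,1.55,13.75,11.42
"Coast, Humber and Vale",6,-7.31,-2.88,5.42,15.89,1.35,1.20,1.53,15.63,11.64
"Leicester, Leicestershire and Rutland",15,-6.25,-2.31,5.81,15.33,1.36,1.18,1.58,15.70,13.33
Cheshire and Merseyside,8,-9.21,-3.51,6.07,15.67,1.37,1.24,1.50,14.97,11.30
Sussex and East Surrey,33,-4.39,-1.81,6.63,15.03,1.37,1.24,1.50,14.90,9.37
Devon,37,-4.45,-1.59,6.84,14.62,1.38,1.22,1.56,14.78,12.15
Gloucestershire,43,-7.41,-3.29,5.95,14.59,1.38,1.17,1.64,14.88,11.40
North West London,27,-3.41,-1.79,6.82,15.98,1.39,1.22,1.59,16.25,10.68
North Central London,28,-3.29,-1.56,6.93,15.93,1.42,1.23,1.64,16.97,9.96
Surrey Heartlands,35,-5.75,-3.05,6.49,15.48,1.42,1.20,1.67,16.16,7.69
"West, North and East Cumbria",2,-9.31,-4.04,4.50,13.78,1.42,1.14,1.76,16.99,12.26
Staffordshire,10,-5.69,-3.39,4.72,14.57,1.43,1.25,1.64,18.17,12.48
Frimley Health,34,-5.31,-2.91,6.24,15.28,1.44,1.19,1.74,16.92,8.77
Hampshire and the Isle of Wight,42,-3.76,-1.48,6.96,14.74,1.44,1.31,1.59,16.86,9.76
Coventry and Warwickshire,18,-6.72,-2.98,5.73,14.97,1.44,1.24,1.67,17.37,12.77
Greater Manchester,7,-9.21,-3.21,5.61,15.84,1.45,1.31,1.60,18.54,12.00
Dorset,41,-3.89,-1.23,7.43,15.44,1.47,1.26,1.71,17.68,10.02
The Black Country,16,-6.43,-2.85,5.46,14.79,1.48,1.31,1.67,18.96,13.86
"Bristol, North Somerset, and South Gloucestershire",39,-5.18,-2.38,6.42,14.25,1.48,1.28,1.70,17.33,10.94
Shropshire and Telford and Wrekin,11,-9.64,-3.48,5.93,15.14,1.48,1.22,1.81,18.12,14.79
Suffolk and North East Essex,23,-6.73,-2.57,5.81,15.63,1.49,1.30,1.71,19.60,8.64
Birmingham and Solihull,17,-7.65,-3.15,5.60,14.95,1.50,1.30,1.72,19.11,14.13
Derbyshire,12,-7.34,-3.43,4.93,15.00,1.50,1.30,1.73,20.27,12.54
Mid and South Essex,26,-5.42,-2.07,6.36,16.20,1.57,1.38,1.80,22.06,6.99
Cornwall and the Isles of Scilly,36,-3.49,-1.16,7.44,14.38,1.71,1.44,2.04,22.14,14.29
Somerset,38,-5.37,-2.30,6.43,14.79,1.74,1.44,2.09,24.31,12.24
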