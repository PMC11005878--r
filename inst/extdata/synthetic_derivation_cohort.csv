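patient_id,age_days,heart_rate,respiratory_rate,crt_seconds,avpu,lactate,glucose,outcome,assigned_score
P0001,246.8,102,21,1.8,A,8.05,3.13,survived,0
P0002,1436.2,171,12,1.6,A,3.39,13.61,survived,1
P0003,3392.8,136,43,5.5,U,20.08,7.09,died,4
P0004,779.6,164,30,2.3,A,57.93,6.74,died,2
P0005,1312.8,71,12,1.6,A,1.2,9.35,survived,0
P0006,4978.9,59,8,1.4,A,14.53,6.77,died,0
P0007,147.3,161,30,2.6,A,1.68,18.93,died,0
P0008,2981.1,74,42,2.1,V,5.28,12.26,survived,2
P0009,532.1,171,33,1.7,P,0.87,17.47,survived,1
P0010,3324.9,73,17,1.3,A,5.88,7.66,survived,0
P0011,300.4,142,49,1.6,P,29.05,15.72,died,2
P0012,3887.3,129,21,1.6,A,11.66,44.52,died,1
P0013,1654.2,81,9,2,A,2.39,9.13,survived,0
P0014,747.3,149,12,1.2,A,3.05,5.82,survived,1
P0015,3007.4,61,26,2.6,A,0.56,12.87,survived,1
P0016,104.8,105,16,1.3,A,3.29,12.49,survived,0
P0017,90.9,137,31,3.7,V,2.53,17.33,died,2
P0018,90.8,57,24,1.2,A,1.45,17.06,died,1
P0019,453,76,44,0.7,A,0.56,8.56,survived,2
P0020,664.3,123,20,5.7,A,62.41,16.95,died,1
P0021,1011.1,140,10,2.6,A,2.34,18.45,survived,0
P0022,255.8,156,50,0.5,P,0.53,7.03,survived,2
P0023,596.1,113,40,2.6,A,2.48,9.54,survived,1
P0024,144.1,141,58,2.6,A,3.21,6.97,died,1
P0025,820.7,65,16,2.3,A,3.12,9.07,died,0
P0026,2888.1,161,8,1.5,A,9.57,10.07,died,1
P0027,611.8,199,30,4.9,A,6.05,18.28,died,2
P0028,144.2,56,47,6,V,24.45,8.63,died,4
P0029,981.1,129,44,5.5,A,1.77,8.96,died,2
P0030,620.8,212,16,2.3,V,1.95,10.05,died,2
P0031,67.3,141,13,2.8,A,8.53,7.47,survived,0
P0032,303.5,222,52,4.8,P,229.96,12.24,died,4
P0033,362.8,160,27,1.6,A,0.68,5.11,survived,0
P0034,1011.5,71,12,4.4,A,4.31,10.17,died,1
P0035,223.4,113,17,1.4,A,0.98,9.75,survived,0
P0036,122.1,187,46,2.8,A,91.99,8.89,died,2
P0037,62.4,110,46,1.4,A,0.84,7.61,survived,1
P0038,2334.9,136,13,4.5,A,30.71,16.19,died,2
P0039,2507.1,115,42,1.3,A,0.65,6.89,survived,1
P0040,594.1,139,33,2,A,0.88,8.41,survived,0
P0041,1356.7,88,21,1.8,A,2.45,5.64,survived,0
P0042,72.4,111,32,2.4,A,0.69,6.05,survived,0
P0043,2296.3,69,34,1,A,2.1,24.71,died,1
P0044,93.7,161,30,2.4,A,2.52,4.94,survived,0
P0045,453.7,133,54,4,A,5.56,40.29,died,2
P0046,94.6,69,14,4.9,V,3.96,9.1,died,3
P0047,122.3,100,41,1.1,A,4.35,5.62,died,1
P0048,1207,130,20,4.4,A,0.71,7.66,survived,1
P0049,1660.2,121,15,0.7,A,4.88,12.39,died,0
P0050,2794.3,146,22,3.5,V,1.78,12.77,died,4
P0051,757.9,179,32,1.5,A,0.59,6.75,died,2
P0052,3174.1,120,14,1,A,3.63,8.64,survived,0
P0053,152,222,32,5,A,15.99,11.23,died,2
P0054,83.3,108,25,1.2,A,3.05,10.53,survived,0
P0055,1144.3,141,44,3.6,V,160.96,9.77,died,4
P0056,235.3,94,33,2.2,A,0.86,6.27,survived,0
P0057,347.6,63,46,4.9,V,1.12,8.83,died,4
P0058,272.5,70,31,5.7,P,5.85,17.86,died,3
P0059,81.6,107,23,1.6,A,2.35,14.09,died,0
P0060,72.9,214,29,3.8,A,4.87,15.43,died,2
P0061,484.5,128,17,0.5,A,4.32,21.54,died,0
P0062,1057,163,12,3.8,A,0.9,6.79,survived,2
P0063,841.6,163,18,4.9,A,9.51,7.48,died,2
P0064,183.8,115,29,2.8,A,2.08,14.26,died,0
P0065,101.7,146,31,1,A,4.32,14.81,died,0
P0066,110,202,55,1.3,P,0.11,8.36,died,3
P0067,2867.4,143,10,0.9,A,1.01,6.6,survived,1
P0068,73.9,133,33,1.6,A,1.49,18.06,survived,0
P0069,5013.4,116,9,3.7,A,0.01,15.56,died,2
P0070,3584.2,161,33,5.9,A,0.13,7.78,survived,3
P0071,3018.1,141,9,4.8,U,8.12,6.87,died,3
P0072,361.7,132,45,0.8,A,1.63,10.58,survived,1
P0073,135.3,220,47,2.1,U,132.24,8.76,died,3
P0074,648,190,33,4.2,A,26.34,16.62,died,2
P0075,188.8,140,31,1.6,A,11.19,6.89,survived,0
P0076,621.6,183,20,5.9,U,0.25,7.17,died,3
P0077,248.9,72,48,2.3,A,2.03,16.01,died,2
P0078,1709,118,11,0.5,A,3.53,5.14,survived,0
P0079,1935,151,43,2.1,P,1.54,14.91,died,3
P0080,2269.8,135,31,3.7,V,5.73,3.68,died,4
P0081,4592.9,114,11,0.5,V,32.42,11.06,died,1
P0082,4015.3,83,14,0.6,A,0.5,4.18,survived,0
P0083,1057.6,82,21,3.4,A,0.31,6.03,survived,1
P0084,4198.9,92,40,0.6,A,56.29,3.52,died,1
P0085,170.4,158,30,2.3,A,1.56,6.48,survived,0
P0086,428.7,108,19,1.7,A,0.32,6.18,survived,0
P0087,2454.4,154,30,3.9,V,5.09,15.98,died,4
P0088,4354.1,124,29,4,A,0.78,5.86,survived,2
P0089,2627.2,173,19,4,V,10.89,8.55,died,4
P0090,614.8,69,55,1,U,9.16,13.68,died,3
P0091,311.1,171,41,2,A,13.77,13.01,died,1
P0092,86.4,102,32,4.5,U,22.82,8.02,died,2
P0093,80.8,82,49,1.1,V,4.52,11.83,died,3
P0094,198.1,216,33,1.1,A,1.6,6.52,died,1
P0095,618.5,154,57,5.7,A,31.96,5.06,died,2
P0096,830.3,111,12,0.8,A,0.62,14.87,survived,0
P0097,1698.4,184,33,4.7,U,1.62,13.36,died,4
P0098,432.2,61,22,3.8,A,2.62,11.59,died,2
P0099,846.3,119,18,4.1,A,3.57,7.13,died,1
P0100,137.9,81,49,4.3,P,4.25,11.03,died,4
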