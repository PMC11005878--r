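patient_id,age_days,heart_rate,respiratory_rate,crt_seconds,avpu,lactate,glucose,outcome,assigned_score
P0001,1685.8,103,45,0.6,A,2.27,14.34,died,1
P0002,2894.4,79,8,6,A,1.66,8.85,survived,1
P0003,614.6,175,14,1.7,V,1.4,6.45,survived,1
P0004,1623.6,133,18,3.3,A,2.26,7.47,survived,1
P0005,138.8,135,42,1.2,A,3.16,10.62,survived,1
P0006,3729.4,124,8,2.5,A,2.49,9.25,survived,0
P0007,887.9,135,8,1.6,A,3.04,7.39,survived,0
P0008,275.9,79,16,2.2,A,1.71,11.55,died,1
P0009,104.5,210,54,3.9,U,4.51,4.35,died,4
P0010,1448.7,130,19,1.6,A,2.78,7.71,survived,0
P0011,457.6,115,13,0.6,V,1.69,7.26,survived,1
P0012,160.8,156,24,1.6,V,2.22,9.81,survived,1
P0013,2444.5,121,11,0.8,A,3.23,9.61,survived,0
P0014,174.3,144,22,1,A,2.81,7.36,survived,0
P0015,846.6,99,11,2,A,2.06,7.97,survived,0
P0016,159.9,164,26,2.1,V,15.89,11.31,died,1
P0017,3183,78,14,2.4,A,2.23,7.31,survived,0
P0018,243.5,224,25,1.9,V,12.67,15.16,died,2
P0019,254.4,67,21,3.9,A,22.47,11.5,died,2
P0020,958.2,124,16,0.8,A,1.51,6.34,survived,0
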