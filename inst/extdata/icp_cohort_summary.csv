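patient_id,n_windows,sensor_distance_cm,heart_rate_bpm,resp_rate_bpm,cardiac_amp_mmHg_m,resp_amp_mmHg_m,amp_ratio
1,21,6.8,78,17,1.59,0.72,2.22
2,56,5.5,51,15,1.52,0.46,3.31
3,53,7.0,67,15,1.83,0.36,5.11
4,105,5.3,59,13,1.11,0.58,1.91
5,89,3.2,59,14,3.23,0.88,3.67
6,55,7.0,74,17,0.86,0.41,2.13
7,60,7.9,53,17,0.93,0.30,3.06
8,27,5.7,54,15,0.99,0.51,1.94
9,36,5.3,64,16,1.09,0.48,2.26
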