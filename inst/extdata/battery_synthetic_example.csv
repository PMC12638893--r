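"participant_id","wave","pas_content","pas_process","social_support","recovery","age","gender","childhood_trauma","smoking","income","n_monitorings"
"p0001","B0",31.15,32,3.63,3.53,40,1,26,2,4,4
"p0002","B0",38.98,37.42,3.79,2.01,32,0,33,4,6,4
"p0003","B0",33.37,33.2,3.55,1.36,30,0,31,1,2,4
"p0004","B0",29.61,27.25,3.77,2.99,34,0,40,0,4,4
"p0005","B0",30.04,34.89,3.28,2.77,30,1,25,1,2,4
"p0006","B0",40.16,33.94,3.57,2.54,35,0,28,2,4,4
"p0001","B1",31.15,31.6,3.63,3.53,40,1,26,2,4,4
"p0002","B1",38.98,43.16,3.79,2.01,32,0,33,4,6,4
"p0003","B1",33.37,26.52,3.55,1.36,30,0,31,1,2,4
"p0004","B1",29.61,27.61,3.77,2.99,34,0,40,0,4,4
"p0005","B1",30.04,30.11,3.28,2.77,30,1,25,1,2,4
"p0006","B1",40.16,33.31,3.57,2.54,35,0,28,2,4,4
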