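"participant_id","time_index","P","E"
"p0001",0,14.56,0.7254
"p0002",0,8.43,0.124
"p0003",0,16.12,-0.4273
"p0004",0,27.29,-0.6322
"p0005",0,1.52,-1.4666
"p0006",0,16.73,0.9863
"p0001",1,23.52,-0.1089
"p0002",1,20.95,0.8448
"p0003",1,23.64,-0.0249
"p0004",1,24.78,-0.7458
"p0005",1,24.75,-1.0494
"p0006",1,23.97,1.2767
"p0001",2,20.56,-0.1944
"p0002",2,21.28,0.2803
"p0003",2,18.49,-0.3492
"p0004",2,23.19,-0.0809
"p0005",2,14.29,-1.2691
"p0006",2,24.73,1.9607
"p0001",3,12.1,0.5839
"p0002",3,27.9,0.5765
"p0003",3,16.26,-0.0249
"p0004",3,20.96,-0.4701
"p0005",3,14.05,-1.3826
"p0006",3,20.61,0.7181
"p0001",4,23.14,0.1873
"p0002",4,21.81,0.7534
"p0003",4,31.43,0.2375
"p0004",4,16.74,-0.3566
"p0005",4,12.36,-1.6863
"p0006",4,9.59,1.0143
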