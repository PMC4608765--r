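subject_id,landmark,x_mm,y_mm
S001,S,0,0
S001,N,65.726,0
S001,A,55.567,-44.091
S001,B,32.464,-94.306
S001,Go,-53.568,-66.552
S001,Pg,35.409,-104.764
S001,Me,32.536,-112.472
S001,Gn,33.972,-108.618
S002,S,0,0
S002,N,55.751,0
S002,A,54.273,-45.156
S002,B,22.702,-94.381
S002,Go,0.671,-78.762
S002,Pg,39.219,-102.063
S002,Me,32.919,-109.349
S002,Gn,36.069,-105.706
S003,S,0,0
S003,N,62.662,0
S003,A,56.745,-44.611
S003,B,39.144,-97.195
S003,Go,-3.087,-73.676
S003,Pg,36.526,-107.295
S003,Me,32.246,-114.83
S003,Gn,34.386,-111.063
S004,S,0,0
S004,N,71.064,0
S004,A,64.146,-44.488
S004,B,43.623,-96.161
S004,Go,-13.442,-74.438
S004,Pg,30.678,-110.058
S004,Me,31.825,-118.259
S004,Gn,31.251,-114.159
S005,S,0,0
S005,N,58.748,0
S005,A,52.763,-44.603
S005,B,30.539,-95.939
S005,Go,-21.517,-66.691
S005,Pg,29.364,-113.424
S005,Me,31.398,-121.734
S005,Gn,30.381,-117.579
S006,S,0,0
S006,N,57.722,0
S006,A,52.221,-44.663
S006,B,35.557,-97.513
S006,Go,-25.068,-60.373
S006,Pg,26.219,-103.266
S006,Me,32.58,-112.107
S006,Gn,29.4,-107.687
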