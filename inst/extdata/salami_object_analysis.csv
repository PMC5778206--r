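sample,statistic,mean,sd,letters
A,n_per_area,1.44,0.2,cd
B,n_per_area,1.10,0.2,a
C,n_per_area,0.99,0.2,a
D,n_per_area,1.19,0.1,ab
E,n_per_area,1.42,0.2,c
F,n_per_area,1.30,0.1,b
G,n_per_area,1.38,0.2,c
H,n_per_area,1.54,0.6,d
I,n_per_area,1.76,0.2,e
J,n_per_area,1.14,0.2,ab
K,n_per_area,1.41,0.2,c
L,n_per_area,1.45,0.4,cd
M,n_per_area,1.40,0.2,c
N,n_per_area,1.29,0.1,b
O,n_per_area,1.87,0.2,e
P,n_per_area,1.68,0.4,de
A,af_mean,0.085,0.01,ab
B,af_mean,0.133,0.02,fg
C,af_mean,0.124,0.02,e
D,af_mean,0.084,0.01,a
E,af_mean,0.083,0.00,a
F,af_mean,0.135,0.03,fg
G,af_mean,0.122,0.02,ef
H,af_mean,0.089,0.01,b
I,af_mean,0.075,0.01,a
J,af_mean,0.099,0.01,bc
K,af_mean,0.112,0.01,cd
L,af_mean,0.085,0.01,ab
M,af_mean,0.123,0.01,ef
N,af_mean,0.118,0.03,de
O,af_mean,0.138,0.01,g
P,af_mean,0.095,0.01,c
A,af_max,0.81,0.5,ab
B,af_max,0.75,0.2,a
C,af_max,1.25,0.0,bc
D,af_max,0.83,0.4,ab
E,af_max,0.69,0.0,a
F,af_max,1.19,0.4,bc
G,af_max,1.01,0.5,b
H,af_max,1.19,0.3,bc
I,af_max,0.90,0.3,ab
J,af_max,0.68,0.2,a
K,af_max,1.60,0.2,d
L,af_max,0.82,0.2,ab
M,af_max,0.91,0.1,ab
N,af_max,1.03,0.2,b
O,af_max,1.33,0.3,c
P,af_max,1.20,0.3,bc
A,rf_mean,1.50,0.5,a
B,rf_mean,1.79,0.3,b
C,rf_mean,2.03,0.3,c
D,rf_mean,1.72,0.0,a
E,rf_mean,1.90,0.1,b
F,rf_mean,1.92,0.0,bc
G,rf_mean,1.93,0.1,bc
H,rf_mean,2.08,0.1,c
I,rf_mean,2.00,0.1,c
J,rf_mean,1.86,0.2,b
K,rf_mean,2.05,0.1,c
L,rf_mean,1.89,0.1,b
M,rf_mean,1.97,0.1,c
N,rf_mean,2.06,0.1,c
O,rf_mean,2.05,0.1,c
P,rf_mean,2.08,0.1,c
A,rf_max,6.16,1.7,bc
B,rf_max,4.41,1.1,ab
C,rf_max,4.77,0.7,ab
D,rf_max,3.89,0.3,a
E,rf_max,4.75,0.5,ab
F,rf_max,4.73,0.2,ab
G,rf_max,4.48,0.5,ab
H,rf_max,7.90,0.1,d
I,rf_max,6.41,0.0,c
J,rf_max,4.91,1.4,b
K,rf_max,6.18,0.5,bc
L,rf_max,5.53,1.3,b
M,rf_max,5.22,0.3,b
N,rf_max,5.71,1.2,bc
O,rf_max,6.32,1.1,c
P,rf_max,7.91,0.1,d
A,vfc,11.84,1.2,b
B,vfc,11.37,1.1,b
C,vfc,14.30,0.9,cd
D,vfc,8.74,1.0,a
E,vfc,11.56,1.5,b
F,vfc,15.64,1.0,d
G,vfc,14.11,1.1,cd
H,vfc,11.33,0.2,b
I,vfc,13.05,2.1,bc
J,vfc,9.75,0.6,a
K,vfc,15.60,1.5,d
L,vfc,12.03,0.8,b
M,vfc,15.33,1.8,d
N,vfc,14.44,0.7,cd
O,vfc,18.52,0.3,e
P,vfc,14.46,1.6,cd
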