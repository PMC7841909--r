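name,F0M,l0M,lTs,alpha0,PCSA
glut_med1,819,0.0535,0.078,0.140,13.4
glut_med2,573,0.0845,0.053,0.000,9.4
glut_med3,653,0.0646,0.053,0.087,10.7
glut_min1,270,0.068,0.016,0.175,4.4
glut_min2,285,0.056,0.026,0.000,4.7
glut_min3,323,0.038,0.051,0.017,5.3
semimem,1288,0.080,0.359,0.262,21.1
semiten,410,0.201,0.262,0.087,6.7
bifemlh,896,0.109,0.341,0.000,14.7
bifemsh,804,0.173,0.100,0.401,13.2
sar,156,0.520,0.040,0.000,2.6
add_long,627,0.138,0.110,0.105,10.3
add_brev,429,0.133,0.020,0.000,7.0
add_mag1,381,0.087,0.060,0.087,6.2
add_mag2,343,0.121,0.120,0.052,5.6
add_mag3,488,0.131,0.249,0.087,8.0
tfl,233,0.095,0.425,0.052,3.8
pect,177,0.133,0.001,0.000,2.9
grac,108,0.352,0.140,0.052,1.8
glut_max1,573,0.142,0.125,0.087,9.4
glut_max2,819,0.147,0.127,0.000,13.4
glut_max3,552,0.144,0.145,0.087,9.0
iliacus,1073,0.100,0.100,0.122,17.6
psoas,1113,0.104,0.130,0.140,18.2
quad_fem,381,0.054,0.024,0.000,6.2
gem,164,0.024,0.039,0.000,2.7
peri,444,0.026,0.115,0.175,7.3
rect_fem,1169,0.114,0.310,0.087,19.2
vas_med,1294,0.089,0.126,0.087,21.2
vas_int,1365,0.087,0.136,0.052,22.4
vas_lat,1871,0.084,0.157,0.087,30.7
med_gas,1558,0.060,0.390,0.297,25.5
lat_gas,683,0.064,0.385,0.140,11.2
soleus,3549,0.050,0.250,0.436,58.2
tib_post,1588,0.031,0.310,0.209,26.0
flex_dig,310,0.034,0.400,0.122,5.1
flex_hal,322,0.043,0.380,0.175,5.3
tib_ant,905,0.098,0.223,0.087,14.8
per_brev,435,0.050,0.161,0.087,7.1
per_long,943,0.049,0.345,0.175,15.5
per_tert,180,0.079,0.100,0.227,3.0
ext_dig,512,0.102,0.345,0.140,8.4
ext_hal,162,0.111,0.305,0.105,2.7
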