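model,condition,nrmse_mean_pct,nrmse_sd_pct,ra2_mean,ra2_sd
PBM,8ch,2.73,0.97,0.85,0.13
PBM,5ch,3.07,1.03,0.86,0.11
PBM,2ch,4.59,1.32,0.77,0.19
OLS,8ch,2.88,0.94,0.84,0.11
OLS,5ch,3.17,1.06,0.77,0.13
OLS,2ch,4.82,1.81,0.63,0.23
RLS,8ch,2.83,0.93,0.82,0.10
RLS,5ch,3.11,1.01,0.79,0.11
RLS,2ch,4.73,1.31,0.69,0.18
SVM,8ch,2.85,1.00,0.82,0.09
SVM,5ch,3.00,1.04,0.80,0.10
SVM,2ch,4.77,1.02,0.73,0.14
ANN,8ch,2.82,0.95,0.82,0.09
ANN,5ch,3.03,1.05,0.81,0.12
ANN,2ch,4.74,1.17,0.69,0.18
LWPR,8ch,3.03,1.14,0.75,0.21
LWPR,5ch,3.19,1.19,0.78,0.13
LWPR,2ch,4.97,1.31,0.69,0.21
PBM,train25,4.41,2.49,0.81,0.09
PBM,train90,2.32,0.59,0.96,0.04
OLS,train25,4.19,2.19,0.80,0.10
OLS,train90,2.19,0.58,0.97,0.04
RLS,train25,4.14,2.13,0.82,0.08
RLS,train90,2.07,0.51,0.97,0.03
SVM,train25,4.39,2.46,0.85,0.09
SVM,train90,2.02,0.92,0.97,0.03
ANN,train25,5.87,2.20,0.73,0.20
ANN,train90,2.34,0.61,0.96,0.03
LWPR,train25,6.41,3.14,0.69,0.29
LWPR,train90,3.43,0.84,0.87,0.07
PBM,after1h,5.28,2.68,0.56,0.24
PBM,after24h,5.54,2.95,0.47,0.26
OLS,after1h,4.84,2.98,0.59,0.27
OLS,after24h,5.29,3.04,0.51,0.25
RLS,after1h,4.81,2.91,0.63,0.23
RLS,after24h,5.19,2.98,0.54,0.27
SVM,after1h,5.35,2.22,0.54,0.21
SVM,after24h,6.76,2.95,0.46,0.28
ANN,after1h,5.40,2.15,0.53,0.28
ANN,after24h,6.44,3.09,0.51,0.31
LWPR,after1h,5.42,3.00,0.60,0.23
LWPR,after24h,5.93,3.18,0.59,0.30
PBM,supinated,9.55,5.69,0.22,0.32
OLS,supinated,8.93,5.37,0.25,0.33
RLS,supinated,8.86,5.30,0.23,0.29
SVM,supinated,8.65,4.47,0.24,0.37
ANN,supinated,9.13,4.76,0.23,0.36
LWPR,supinated,10.05,5.49,0.25,0.30
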