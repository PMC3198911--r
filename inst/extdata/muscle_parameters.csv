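muscle,role,fmax_mean_N,fmax_sd_N,ma_mean_m,ma_sd_m,pcsa_cm2,represents,represented_pcsa_cm2
ECRL,extensor,304,61,-0.017,0.004,2.4,,0
EDC,extensor,120,30,-0.012,0.003,3.3,EDM;EIP;EPL,2.2
ECU,extensor,122,25,-0.011,0.003,3.4,,0
ECRB,extensor,100,25,-0.014,0.003,2.9,,0
FCR,flexor,74,20,0.015,0.003,2.0,,0
PL,flexor,43,12,0.012,0.003,1.2,FPL,4.1
FDS,flexor,210,50,0.012,0.003,6.0,FDP,11.0
FCU,flexor,122,30,0.019,0.004,3.4,,0
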