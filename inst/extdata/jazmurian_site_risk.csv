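city,sample,hi_adult,hi_child,cr_adult,cr_child
Jiroft,D1,1.19,5.28,1.33e-4,1.60e-3
Jiroft,D2,1.36,6.05,1.22e-4,1.46e-3
Jiroft,D3,1.38,6.13,0.85e-4,1.02e-3
Roodbar Jonoob,D4,1.33,5.91,1.25e-4,1.49e-3
Roodbar Jonoob,D5,1.23,5.46,1.11e-4,1.32e-3
Ghaleh-Ganj,D6,1.06,4.70,1.67e-4,2.00e-3
Ghaleh-Ganj,D7,1.06,4.73,1.14e-4,1.36e-3
Kahnooj,D8,0.71,3.19,1.05e-4,1.26e-3
Kahnooj,D9,1.11,4.93,0.91e-4,1.09e-3
Iranshahr,D10,1.09,4.85,1.59e-4,1.90e-3
Iranshahr,D11,1.19,5.28,4.17e-4,4.99e-3
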