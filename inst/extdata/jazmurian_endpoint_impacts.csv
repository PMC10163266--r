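category,unit,scale,D1,D2,D3,D4,D5,D6,D7,D8,D9,D10,D11
human carcinogenic toxicity,DALY,1e-10,7.08,6.59,4.53,6.63,5.79,8.42,5.88,3.96,4.69,7.72,19.0
human non-carcinogenic toxicity,DALY,1e-10,9.62,9.62,9.43,8.44,5.90,6.16,7.17,7.38,7.39,6.95,11.2
freshwater ecotoxicity,species.yr,1e-15,1.41,1.41,1.57,1.86,1.38,1.63,1.46,2.65,1.78,1.19,1.38
marine ecotoxicity,species.yr,1e-15,6.97,6.96,7.00,12.1,7.53,6.74,6.65,23.1,10.7,5.51,5.76
terrestrial ecotoxicity,species.yr,1e-12,1.43,1.43,1.38,2.73,1.60,1.27,1.29,5.62,2.37,1.11,1.08
human health total,DALY,1e-10,16.7,16.2,13.9,15.1,11.7,14.6,13.0,11.3,12.1,14.6,30.2
ecological total,species.yr,1e-12,1.43,1.43,1.38,2.73,1.60,1.27,1.29,5.62,2.37,1.11,1.08
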