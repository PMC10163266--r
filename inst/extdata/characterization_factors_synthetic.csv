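element,category,factor
Cr(VI),human carcinogenic toxicity,4.4e-2
As,human carcinogenic toxicity,1.3e-2
Ni,human carcinogenic toxicity,1.0e-3
Co,human carcinogenic toxicity,5.0e-3
Cd,human carcinogenic toxicity,2.0e-2
Pb,human carcinogenic toxicity,1.0e-4
As,human non-carcinogenic toxicity,3.0e-2
Zn,human non-carcinogenic toxicity,3.0e-3
Mn,human non-carcinogenic toxicity,5.0e-4
Pb,human non-carcinogenic toxicity,5.0e-3
Ni,human non-carcinogenic toxicity,4.0e-4
Cu,human non-carcinogenic toxicity,1.0e-4
Cd,human non-carcinogenic toxicity,1.0e-2
Cr(VI),human non-carcinogenic toxicity,1.0e-3
Cu,terrestrial ecotoxicity,2.0e-5
Ni,terrestrial ecotoxicity,5.0e-6
Zn,terrestrial ecotoxicity,2.0e-6
Cr(VI),terrestrial ecotoxicity,1.0e-6
Pb,terrestrial ecotoxicity,5.0e-7
Cu,marine ecotoxicity,1.0e-7
Ni,marine ecotoxicity,3.0e-8
Zn,marine ecotoxicity,1.0e-8
Cu,freshwater ecotoxicity,2.0e-8
Zn,freshwater ecotoxicity,3.0e-9
Ni,freshwater ecotoxicity,3.0e-9
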