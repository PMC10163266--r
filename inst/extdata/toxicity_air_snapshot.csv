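element,rfc,iur,source
Cr(VI),1.0e-4,8.4e-2,RSL-style snapshot 2024-11; RfC IRIS particulates; IUR IRIS
Cr(III),8.0,NA,route-extrapolated from oral RfD 1.5 mg/kg-day (demonstration)
As,1.5e-5,4.3e-3,RSL-style snapshot 2024-11; RfC CalEPA REL; IUR IRIS
Co,6.0e-6,9.0e-3,RSL-style snapshot 2024-11; PPRTV
Ni,1.4e-5,2.6e-4,RSL-style snapshot 2024-11; RfC CalEPA REL soluble Ni; IUR refinery dust
Mn,5.0e-5,NA,RSL-style snapshot 2024-11; IRIS
Zn,1.6,NA,route-extrapolated from oral RfD 0.3 mg/kg-day (demonstration)
Cu,2.1e-1,NA,route-extrapolated from oral RfD 0.04 mg/kg-day (demonstration)
Pb,1.9e-2,1.2e-5,RfC route-extrapolated from oral RfD (demonstration); IUR CalEPA
Cd,1.0e-5,1.8e-3,RSL-style snapshot 2024-11; RfC ATSDR MRL; IUR IRIS
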