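receptor,inhr,ef,ed,bw,at_nc,at_ca
adult,15,350,26,80,9490,25550
child,12.5,350,6,15,2190,25550
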