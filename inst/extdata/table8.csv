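genus,Abaam,Pramkese
Anopheles,3,31
Aedes,6,31
Culex,344,367
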