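site,week_index,genus,sex,count
Abaam,1,Anopheles,unknown,3
Abaam,1,Aedes,unknown,6
Abaam,1,Culex,unknown,344
Pramkese,1,Anopheles,unknown,31
Pramkese,1,Aedes,unknown,31
Pramkese,1,Culex,unknown,367
Pramkese,1,Mansonia,unknown,1
unspecified,1,non_target,unknown,181
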