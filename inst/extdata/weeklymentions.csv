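week,abaam,pramkese
1,45,84
2,29,77
6,54,16
8,0,33
9,0,44
11,82,17
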