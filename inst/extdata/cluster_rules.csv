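species,yellow,red,blue,pink,teal,green
ADG,>10,,,,,>50
CHA,,50-100,,,<10,<30
GON,,>50,,,10-40,NO
AJH,,10-50,NO,20-100,,
JUZ,,10-50,<10,20-100,,NO
PHU,NO,,NO,,>80,NO
STN,<20,>50,NO,<60,<50,<50
TBR,<10,,>50,<40,<5,<30
CUR,,10-50,<10,20-100,,<25
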