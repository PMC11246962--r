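accession_id,yellow,red,blue,pink,teal,green,species_prediction
706032,0,0.565,0,0,0.434,0,GON
706214,0.001,0.704,0,0,0.295,0,GON
706669,0,0.672,0,0,0.327,0,GON
706747,0,0.847,0,0,0.152,0,GON
706831,0,0,0,0,1,0,PHU
705211,0.001,0,0.02,0.218,0.003,0.758,ADG
705260,0.021,0.002,0.441,0.011,0.004,0.522,ADG
705315,0.103,0.002,0,0.007,0.003,0.885,ADG
705328,0.068,0.115,0,0.022,0.075,0.72,ADG
707848,0.089,0.151,0.071,0.506,0.001,0.182,CUR
709027,0.002,0.006,0.792,0.101,0.003,0.096,TBR
709028,0.002,0.02,0.802,0.002,0.001,0.173,TBR
709029,0.002,0.019,0.801,0.003,0.003,0.172,TBR
709031,0.002,0.018,0.807,0.001,0.003,0.168,TBR
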