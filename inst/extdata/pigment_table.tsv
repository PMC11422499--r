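name	abbreviation	retention_time_min	absorption_maxima_nm
Chlorophyll c3	Chlc3	3.7	456, 588, (626)
Chlorophyll c2	Chlc1c2	5.9	446, 584, 634
Chlorophyll c1		6.2	442, 580, 632
Chlorophyllide a	Chlidea	6.3	(380), 434, 620, 666
Pheophorbide a	Phidea	8.1	410, 508, 538, 610, 666
Peridinin	Peri	10.0	476
19' Butanoyloxyfucoxanthin	But	13.6	448, 468
Fucoxanthin	Fuco	14.0	452
Loroxanthin-like	Loro	14.9	(422), 446, 474
Neoxanthin	Neo	15.1	412, 436, 464
Prasinoxanthin	Pras	15.3	458
Violaxanthin	Viola	15.6	416, 440, 468
19' Hexanoyloxyfucoxanthin	Hex	15.9	446, 468
Diadinoxanthin	Diad	17.2	(424), 446, 474
Alloxanthin	Allo	18.7	(428), 450, 480
Diatoxanthin	Diato	19.5	(428), 450, 478
Zeaxanthin	Zea	20.3	(428), 450, 476
Lutein	Lut	20.6	(422), 444, 472
Gyroxanthin diester	Gyro	23.4	(424), 444, 470
Divinyl Chlorophyll b	DVChlb	25.6	478, 606, 656
Monovinyl Chlorophyll b	Chlb	25.7	468, 602, 650
Divinyl Chlorophyll a	DVChla	28.1	(390), 440, 624, 666
Monovinyl Chlorophyll a	Chla	28.3	(388), 432, 618, 666
Pheophytin a	Phytina	30.2	408, 506, 536, 608, 666
beta,epsilon-carotene	Caro	31.2	(422), 444, 472
beta,beta-carotene	Caro	31.3	(428), 452, 476
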