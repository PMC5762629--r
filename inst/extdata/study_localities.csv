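"name","region","latitude","longitude","altitude"
"Eilot","Eilat",29.5835,34.9604,89
"Elifaz","Eilat",29.7928,35.0106,121
"Samar","Eilat",29.8294,35.0238,92
"Yotvata","Eilat",29.8995,35.0596,86
"Grofit","Eilat",29.9393,35.0635,141
"Faran","Negev",30.3776,35.1503,94
"Idan","Negev",30.814,35.2768,-174
"Tlalim","Negev",30.9929,34.7735,364
"Gilat","Negev",31.3225,34.6507,138
"Avigdor","Center",31.7094,34.7439,65
"Ramat Rachel","Center",31.741,35.2165,809
"Ma'ale Hahamisha","Center",31.8197,35.1115,805
"Hulda","Center",31.8293,34.8818,121
"Gaash","Center",32.2323,34.8252,23
"Beit Alfa","North",32.5171,35.4315,-85
"Ein Hamifratz","North",32.904,35.0972,6
"Amir","North",33.177,35.6236,76
"Dafna","North",33.2299,35.6421,141
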