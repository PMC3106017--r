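t,x,y
0.00000000000000000,4.9651298038289768,10.908054183540656
0.96138114078698744,5.1803932569176494,12.090570024976433
1.92276228157397489,5.3830114243974885,13.306040259168023
2.88414342236096211,5.5740734523605546,14.548669250892820
3.84552456314794977,5.7546684868989022,15.812661364928205
4.80690570393493743,5.9258856741045882,17.092220966051563
5.76828684472192421,6.0888141600696697,18.381552419040283
6.72966798550891188,6.2445430908862063,19.674860088671750
7.69104912629589954,6.3941616126462524,20.966348339723343
8.65243026708288632,6.5387588714418650,22.250221536972461
9.61381140786987487,6.6794240133651028,23.520684045196479
10.57519254865686165,6.8172461845080230,24.771940229172788
11.53657368944384842,6.9533145309626798,25.998194453678774
12.49795483023083698,7.0887181988211330,27.193651083491815
13.45933597101782375,7.2245463341754395,28.352514483389307
14.42071711180481230,7.3618880831176545,29.468989018148637
15.38209825259179908,7.5018325917398361,30.537279052547177
16.34347939337878586,7.6454690061340402,31.551588951362326
17.30486053416577263,7.7938864723923240,32.506123079371456
18.26624167495276296,7.9481741366067471,33.395085801351968
19.22762281573974974,8.1094211448693674,34.212681482081251
20.18900395652673652,8.2787166432722348,34.953114486336673
21.15038509731372329,8.4571497779074107,35.610589178895623
22.11176623810071007,8.6458096948669567,36.179309924535509
23.07314737888769685,8.8457855402429200,36.653481088033679
24.03452851967468717,9.0581664601273690,37.027307034167556
24.99590966046167395,9.2840416006123494,37.294992127714494
25.95729080124866073,9.5245001077899278,37.450740733451916
26.91867194203564750,9.7806311277521552,37.488757216157168
27.88005308282263428,10.0344869118280950,37.369720807888697
28.84143422360962461,10.2680073635864169,37.067451333279969
29.80281536439661139,10.4821131074785914,36.595864045970963
30.76419650518359816,10.6777247679560858,35.968874199601657
31.72557764597058494,10.8557629694703710,35.200397047812018
32.68695878675757172,11.0171483364729159,34.304347844242031
33.64833992754456204,11.1628014934151842,33.294641842531654
34.60972106833154527,11.2936430647486521,32.185194296320866
35.57110220911853560,11.4105936749247867,30.989920459249646
36.53248334990552593,11.5145739483950571,29.722735584957963
37.49386449069250915,11.6065045096109305,28.397554927085800
38.45524563147949948,11.6873059830238777,27.028293739273124
39.41662677226648270,11.7578989930853677,25.628867275159909
40.37800791305347303,11.8192041642468713,24.213190788386125
41.33938905384046336,11.8721421209598539,22.795179532591746
42.30077019462744659,11.9176334876757863,21.388748761416764
43.26215133541443691,11.9565988888461376,20.007813728501130
44.22353247620142014,11.9899589489223803,18.666289687484838
45.18491361698841047,12.0186342923559764,17.378091892007838
46.14629475777539369,12.0435455435984018,16.157135595710120
47.10767589856238402,12.0656133271011221,15.017336052231659
48.06905703934937435,12.0857582673156063,13.972608515212427
49.03043818013635757,12.1049009886933234,13.036868238292392
49.99181932092334790,12.1239621156857460,12.224030475111531
50.95320046171033113,12.1438622727443413,11.548010479309818
51.91458160249732146,12.1655220843205747,11.022723504527239
52.87596274328431178,12.1898621748659206,10.662084804403737
53.83734388407129501,12.2178031688318445,10.480009632579321
54.79872502485828534,12.3834305825350341,10.412784882704463
55.76010616564526856,12.7968872852832991,10.391275855301989
56.72148730643225889,13.4231799310147988,10.421265414320375
57.68286844721924922,14.2273151736676944,10.508536423708092
58.64424958800623244,15.1742996671801436,10.658871747413619
59.60563072879322277,16.2291400654903022,10.878054249385421
60.56701186958020600,17.3568430225363315,11.171866793571986
61.52839301036719633,18.5224151922563891,11.546092243921775
62.48977415115418665,19.6908632285886362,12.006513464383268
63.45115529194116988,20.8271937854712270,12.558913318904937
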