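country,year,fractures,fractures_per_100k,cost_millions,cost_per_100k
BE,2020,48700,5352,343,37.7
BE,2025,51500,5247,365,37.2
BE,2030,56597,5244,401,37.2
BE,2035,63674,5354,448,37.7
BE,2040,70190,5517,494,38.8
FR,2020,303133,5266,4628,80.4
FR,2025,328918,5125,5026,78.3
FR,2030,370321,5237,5654,80.0
FR,2035,420066,5440,6399,82.9
FR,2040,462294,5606,7042,85.4
DE,2020,409939,5382,4473,58.7
DE,2025,429444,5365,4686,58.6
DE,2030,447562,5240,4883,57.2
DE,2035,484442,5131,5304,56.2
DE,2040,541024,5270,5903,57.5
IE,2020,14768,5540,132,49.7
IE,2025,17469,5526,155,49.1
IE,2030,20952,5652,185,50.0
IE,2035,24642,5728,218,50.6
IE,2040,28494,5846,250,51.3
PL,2020,85578,3048,235,8.4
PL,2025,95823,2892,264,8.0
PL,2030,111468,2924,307,8.0
PL,2035,128478,3192,352,8.7
PL,2040,140632,3450,383,9.4
SK,2020,16868,4648,48,13.2
SK,2025,19586,4526,56,13.0
SK,2030,23181,4681,65,13.2
SK,2035,26279,4893,74,13.7
SK,2040,28028,5020,78,14.0
CH,2020,50952,7656,744,111.9
CH,2025,56590,7813,824,113.8
CH,2030,63088,7903,918,115.0
CH,2035,70596,7851,1028,114.3
CH,2040,78878,7918,1148,115.3
GB,2020,308381,6068,2187,43.0
GB,2025,339412,6199,2405,43.9
GB,2030,372077,6291,2634,44.5
GB,2035,406832,6283,2880,44.5
GB,2040,434760,6290,3078,44.5
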