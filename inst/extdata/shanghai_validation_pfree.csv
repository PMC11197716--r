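crop,observed_acreage_ha,modeled_acreage_ha,observed_production_t,modeled_production_t,observed_price_yuan_per_kg,modeled_price_yuan_per_kg
rice,85656,83627,841000,719832,4.35,4.304
wheat,38397,35158,199200,163344,2.76,3.225
barley,7183,8209,45200,37064,2.55,2.834
melon,6937,7264,264500,216890,5.52,5.444
rapeseed,3873,4322,9600,9381,3.04,3.093
strawberry,1276,1250,22100,21437,15.00,15.001
fruit,20067,20198,326900,317093,9.28,8.977
leafy,52125,52764,1404000,1361880,2.50,2.476
pekinensis,3361,3283,163500,158595,1.41,1.461
cabbage,11154,14255,550500,533985,1.43,1.493
root,5587,5494,190700,184979,1.63,1.695
cucurbit,5977,5959,244900,237553,4.16,4.192
beans,10406,9552,226700,219899,6.12,6.168
solanaceae,7912,8043,300900,291873,5.01,5.011
allium,1964,2498,76500,74205,2.66,2.59
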