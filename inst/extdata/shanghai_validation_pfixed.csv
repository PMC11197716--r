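crop,observed_acreage_ha,modeled_acreage_ha,observed_production_t,modeled_production_t,observed_price_yuan_per_kg,modeled_price_yuan_per_kg
rice,85656,87414,841000,753873,4.35,4.350
wheat,38397,35598,199200,164737,2.76,2.760
barley,7183,8009,45200,36160,2.55,2.717
melon,6937,7545,264500,226542,5.52,5.520
rapeseed,3873,3944,9600,8701,3.04,3.038
strawberry,1276,1143,22100,19774,15.00,14.997
fruit,20067,21161,326900,337969,9.28,9.276
leafy,52125,50911,1404000,1339755,2.50,2.501
pekinensis,3361,3118,163500,146749,1.41,1.410
cabbage,11154,12998,550500,484307,1.43,1.430
root,5587,5265,190700,174143,1.63,1.630
cucurbit,5977,5669,244900,224788,4.16,4.161
beans,10406,9485,226700,210744,6.12,6.118
solanaceae,7912,7260,300900,268735,5.01,5.010
allium,1964,2354,76500,70363,2.66,2.660
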