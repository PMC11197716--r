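variable,overall,non_mechanized,mechanized
yield_kg_per_ha,8064.94,7943.18,8085.23
fertilizer_kg_per_ha,997.40,1009.09,995.45
pesticide_kg_per_ha,18.00,18.75,17.87
labor_wage_yuan_per_pm,1915.58,1863.64,1924.24
labor_pm_per_ha,13.58,14.83,13.37
machinery_purchase_cost_annualized_yuan_per_ha,2200.30,1794.70,2267.90
machinery_rent_yuan_per_ha,2288.96,2147.73,2312.50
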