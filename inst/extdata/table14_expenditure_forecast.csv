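period,year,gdp_billion_2018usd,expenditure_mm_2018usd
2007-2016 average,NA,16674,3080
2020,2020,19090,3088
2030,2030,23859,3165
2040,2040,29253,3237
2050,2050,35051,3302
2060,2060,41589,3364
2070,2070,48864,3424
2080,2080,56849,3482
2090,2090,65477,3536
2100,2100,74688,3588
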