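region,year,persons
UN-MDR,2014,1.268e+09
UN-MDR,2015,1268800000
UN-MDR,2016,1269600000
UN-MDR,2017,1270400000
UN-MDR,2018,1271200000
UN-MDR,2019,1.272e+09
UN-MDR,2020,1272800000
UN-MDR,2021,1273600000
UN-MDR,2022,1273300000
UN-MDR,2023,1.273e+09
UN-MDR,2024,1272700000
UN-MDR,2025,1272400000
UN-MDR,2026,1272100000
UN-MDR,2027,1271800000
UN-MDR,2028,1271500000
UN-MDR,2029,1271200000
UN-MDR,2030,1270900000
UN-MDR,2031,1270600000
UN-MDR,2032,1270300000
UN-MDR,2033,1.27e+09
UN-MDR,2034,1269700000
UN-MDR,2035,1269400000
UN-MDR,2036,1269100000
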