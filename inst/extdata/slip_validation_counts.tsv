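subject	slips_detected	slips_total	steps_correct	steps_total	se_pct_printed	sp_pct_printed	dt_mean_ms	dt_sd_ms	dt_max_ms	dt_min_ms
1	9	10	386	389	90.00	99.22	369.83	97.49	536.11	202.02
2	10	10	292	297	100.00	98.32	436.72	86.66	634.21	371.15
3	9	10	308	312	90.00	98.71	299.76	107.99	432.00	194.60
4	9	10	339	344	90.00	98.55	355.85	151.38	581.35	198.73
5	9	10	370	372	90.00	99.46	446.72	112.89	626.45	374.36
6	10	10	374	377	100.00	99.20	314.82	105.34	501.23	160.42
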