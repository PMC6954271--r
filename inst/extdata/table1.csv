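method,case,sim_area_cm2,surface_area_cm2,coverage_pct,elapsed_min
manual,21,18.58,96.90,19.17,39
manual,22,28.63,86.16,33.23,53
manual,25,12.62,57.20,22.06,39
manual,27,21.99,64.60,34.04,42
manual,28,18.84,68.80,27.38,42
manual,30,25.19,76.48,32.94,46
manual,31,12.25,65.70,18.65,35
manual,33,16.80,56.70,29.63,34
manual,38,24.48,71.64,34.17,43
manual,40,27.97,64.12,43.62,46
manual,41,22.36,66.72,33.51,42
manual,42,25.14,55.21,45.54,43
manual,43,29.92,54.44,54.96,40
manual,44,23.20,58.04,39.97,49
manual,45,21.33,70.64,30.20,58
apps,57,26.63,,,39
apps,58,30.64,,,32
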