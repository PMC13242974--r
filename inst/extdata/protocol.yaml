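# Standard air-jet indentation protocol: 5 s baseline, 5 s pressure,
# 5 s recovery through a 2 mm nozzle at 50 kPa gauge pressure.
pre_s: 5
on_s: 5
post_s: 5
pressure_pa: 50000
nozzle_diameter_mm: 2
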