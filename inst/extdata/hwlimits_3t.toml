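# Hardware-limits profile for a representative 3 T whole-body system.
# SI units: T, T/m, T/m/s, s.
[limits]
max_rf = 20e-6
rf_dead_time = 100e-6
rf_ringdown_time = 60e-6
rf_raster_time = 1e-6
max_gradient = 0.050
max_slew = 200
grad_raster_time = 10e-6
adc_dead_time = 20e-6
adc_raster_time = 100e-9
block_duration_raster = 10e-6
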