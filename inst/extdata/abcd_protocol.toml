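# ABCD-matched SMS-EPI protocol: 2.4 mm isotropic, 90x90 matrix, 60 slices,
# SMS factor 6, TR 0.8 s, partial Fourier 0.8, CAIPI FOV/3 shift.
[protocol]
fov = [0.216, 0.216, 0.144]     # m
matrix = [90, 90]
n_slices = 60
slice_thickness = 0.0024        # m
sms_factor = 6
tr = 0.8                        # s
partial_fourier = 0.8
flip_angle_deg = 52
n_volumes = 5
caipi_shift = 3
pns_derate = 0.8
n_dummies = 2
n_navigators = 3
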