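# Typical bench DLS configuration: He-Ne laser into water at 22 C,
# 90 degree detection, 16 kHz acquisition. All values SI; the angle
# may alternatively be given in degrees as `scattering_angle_deg`.
wavelength_vacuum: 633.0e-9
refractive_index: 1.331
scattering_angle_deg: 90
temperature: 295.15
viscosity: 9.5e-4
sampling_frequency: 16000
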