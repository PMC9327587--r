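# Example canopyflux run configuration (flat keys; all optional).
latitude: 32.076
longitude: 118.81
days: 166
hours: 12
synthetic: conifer
seed: 1
beam_spacing: 0.2
mesh_spacing: 1.36
source_height: 100
ozone_cm: 0.35
water_cm: 4.0
visibility_km: 7
ground_albedo: 0.2
omega_o: 0.9
forward_fraction: 0.84
urban_factor: 0.79
solar_constant: 1367
reflectance_conifer: 0.25
reflectance_broadleaf: 0.17
transmittance_conifer: 0.15
transmittance_broadleaf: 0.20
refraction_index: 0.5
out_dir: canopyflux_run
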