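# Shared fixtures: the standard 0.6 g water + 0.1 g nanoparticle suspension
# in the acrylic holder, and a mid-range radiating parameter set.

water_np_suspension <- function() {
  suspension(list(constituent(0.6, 4.186, "water"),
                  constituent(0.1, 0.670, "nanoparticles")),
             m_np = 0.1, emissivity = 0.9)
}

std_params <- function(slp = 1.5, eps_eff = 0.008, emissivity = 0.9,
                       t_air = 298) {
  thermal_params(slp = slp, eps_eff = eps_eff, c_susp = 2.5786, m_np = 0.1,
                 emissivity = emissivity, a_t = 9.10e-4, t_air = t_air)
}

std_geometry <- function() {
  holder_geometry(r_int = 5.0e-3, r_ext = 6.0e-3, wall_thickness = 1.0e-3,
                  kappa_sh = 0.2, fill_height = 7.64e-3)
}

# Geometry whose explicit areas reproduce the reference convection
# conductances (0.0048 and 0.0024 W/K at h_air = 8).
reference_area_geometry <- function() {
  holder_geometry(r_int = 5.0e-3, r_ext = 6.0e-3, wall_thickness = 1.0e-3,
                  kappa_sh = 0.2,
                  a_side = 2 * pi * 5.0e-3 * 7.64e-3,
                  a_bottom = pi * 5.0e-3^2,
                  a_sh_ext = 6.0e-4, a_top = 3.0e-4)
}
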