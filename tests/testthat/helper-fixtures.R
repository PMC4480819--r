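# Compact phantom used across tests: 32-cube, 5 mm voxels, one tumour with
# optional rim and necrotic core. 160 mm field of view, ~0.66 L liver.
small_phantom_spec <- function(radius = 20, rim_width = 0, core = 0,
                               centre_off = c(0, 0, 0),
                               noise = "none", psf_sigma = 0, seed = 1L, ...) {
  centre <- c(80, 80, 80) + centre_off
  phantom_spec(grid_shape = c(32L, 32L, 32L), voxel_spacing = c(5, 5, 5),
               liver_semi_axes = c(70, 60, 50),
               tumours = list(phantom_tumour(centre = centre, radius = radius,
                                             rim_width = rim_width,
                                             necrotic_core_radius = core)),
               noise = noise, psf_sigma = psf_sigma, seed = seed, ...)
}

# Minimal dose_report stand-in for exercising the planning classifier.
fake_dose_report <- function(d_t, d_fl_tot) {
  structure(list(administered_activity_gbq = 1, D_T = d_t,
                 D_FL_IR = d_fl_tot, D_FL_TOT = d_fl_tot, D_FL_UN = 0,
                 ratio_T_FL = if (d_fl_tot > 0) d_t / d_fl_tot else NA_real_,
                 volumes = NULL, activity_fractions = NULL),
            class = "dose_report")
}

# Outcome fixture reshaped into the 5x2 contingency tables (responders /
# non-responders, grade 3-4 / lower) used by the between-group tests.
fixture_response_table_3m <- function(fx) {
  cbind(fx$responders_3m, fx$evaluable_3m - fx$responders_3m)
}

fixture_toxicity_table <- function(fx) {
  cbind(fx$grade34, fx$toxicity_evaluable - fx$grade34)
}
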