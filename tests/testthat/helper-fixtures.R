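# Cohort-mean warm-up constants used as generator ground truth throughout the
# suite (also available as cohort_reference_fit()).
ref_constants <- list(tau_mean = 55.3, tau_surface = 41.4, tau_core = 76.8,
                      delta_surface = 0.07, delta_core = 0.04)

# One shared end-to-end run on the default phantom: several test files and
# the acceptance checks inspect different aspects of the same analysis.
default_unit_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_unit(seed = 42L)
    cache
  }
})

# Small, fast diffusion configuration for property checks.
small_box_spec <- function(...) {
  args <- list(grid_dim = c(14, 11, 8), voxel_mm = c(4, 4, 4),
               pouch_height_cm = 4, pouch_width_cm = 2.4,
               pouch_depth_cm = 2, corner_radius_cm = 0,
               sagm_layer_fraction = 0)
  do.call(pouch_phantom_spec, utils::modifyList(args, list(...)))
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
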