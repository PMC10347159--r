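# The stated synthetic world used by the acceptance suite: a 20-target,
# 2-standard roster over a ~600 s chromatogram (minimum spacing 5 s), a
# library of 6 characterized drift conditions (linear scales 0.98-1.02,
# alternating curvature, 1 s wobble), and sample conditions drawn as small
# bounded perturbations of a characterized condition (within-envelope) or as
# a two-trajectory extrapolation beyond it (out-of-envelope).

make_world <- function(seed) {
  w <- simulate_roster(20, 2, span = 600, min_gap = 5, seed = seed)
  conds <- default_drift_conditions(base_seed = seed * 100L)
  lib <- simulate_library(w$base, w$roster, conds)
  list(roster = w$roster, base = w$base, conds = conds, lib = lib,
       span = max(w$base$rts) * 1.05)
}

# a condition inside the library's envelope: a characterized condition with
# bounded parameter jitter (|d scale| <= 1e-3, |d curvature| <= 5e-4) and the
# same wobble realization; total trajectory mismatch to the parent stays
# below ~1 s, mirroring a run that approximately reproduces a characterized
# state
draw_inenv_model <- function(world, rng_fn = stats::runif) {
  ci <- sample(nrow(world$conds), 1)
  drift_model(world$conds$linear_scale[ci] + rng_fn(1, -1e-3, 1e-3),
              world$conds$curvature[ci] + rng_fn(1, -5e-4, 5e-4),
              world$conds$wobble_amplitude[ci],
              seed = world$conds$seed[ci], span = world$span)
}
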