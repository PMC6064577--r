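# Shared fixtures.  The full default experiment takes ~1 min, so it is run
# once per session and cached for every test that needs it.

.fixture_cache <- new.env(parent = emptyenv())

default_run <- function() {
  if (is.null(.fixture_cache$run)) {
    .fixture_cache$run <- run_experiment(experiment_config())
  }
  .fixture_cache$run
}

# A vertical-step scene: left half canopy, right half sky.
step_scene <- function(n = 64) {
  occ <- matrix(0, n, n)
  occ[, (n %/% 2 + 1):n] <- 1
  scene_from_occupancy(occ, pixel_scale = 1, id = "step")
}

# Table of separation width W (mm) and border length per area B (mm/mm^2)
# for the 17-canopy suite, as printed in the published design (2 dp).
published_design <- function() {
  tab <- rbind(
    c(0.05, 2.5,   8.68, 0.08),
    c(0.05, 5.0,  17.36, 0.04),
    c(0.05, 10.0, 34.72, 0.02),
    c(0.10, 2.5,   5.41, 0.16),
    c(0.10, 5.0,  10.81, 0.08),
    c(0.10, 10.0, 21.62, 0.04),
    c(0.25, 2.5,   2.50, 0.40),
    c(0.25, 5.0,   5.00, 0.20),
    c(0.25, 10.0, 10.00, 0.10),
    c(0.25, 20.0, 20.00, 0.05),
    c(0.50, 2.5,   1.04, 0.80),
    c(0.50, 5.0,   2.07, 0.40),
    c(0.50, 10.0,  4.14, 0.20),
    c(0.50, 20.0,  8.28, 0.10),
    c(0.75, 5.0,   0.77, 0.60),
    c(0.75, 10.0,  1.55, 0.30),
    c(0.75, 20.0,  3.09, 0.15)
  )
  colnames(tab) <- c("gf", "L", "W", "B")
  as.data.frame(tab)
}

# Half-up rounding to `digits` decimals (the convention of the printed
# design table, e.g. 1.0355 -> 1.04).
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}
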