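# Shared fixtures, computed lazily and cached for the whole test run.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# default-noise simulation config without truncation
fx_sim_config <- function(...) sim_config(truncation_fraction = 0, ...)

# fully deterministic config: no positional/timing/pose/size noise
fx_zero_noise_config <- function() {
  sim_config(
    positional_sd_um = 0, timing_cv = 0, pose_jitter_deg = 0,
    ab_size_sd = c(wild_type = 0, control = 0, equalized_alive = 0,
                   equalized_dead = 0, inverted = 0),
    compression_sd_um = 0, truncation_fraction = 0)
}

fx_controls <- function() fx_get("controls", function() {
  cfg <- fx_sim_config()
  setNames(lapply(1:4, function(i) simulate_embryo(cfg, "control", 500 + i,
                                                   embryo_id = paste0("ctrl", i))),
           paste0("ctrl", 1:4))
})

fx_reference <- function() fx_get("reference", function() {
  build_reference(fx_controls())
})

# identical (zero-noise) controls and the reference built from them
fx_identical_controls <- function() fx_get("identical_controls", function() {
  cfg <- fx_zero_noise_config()
  setNames(lapply(1:3, function(i)
    simulate_embryo(cfg, "control", 900 + i, embryo_id = paste0("z", i))),
    paste0("z", 1:3))
})

fx_zero_reference <- function() fx_get("zero_reference", function() {
  build_reference(fx_identical_controls())
})

# hand-built minimal embryo in the canonical frame: elongated along x,
# MS-lineage cells ventral (+y). Valid tree: AB,P1 -> 4-cell -> EMS
# divides into MS,E with an L-R division component.
fx_toy_embryo <- function() {
  row <- function(cell, f, x, y, z, parent)
    data.frame(cell = cell, frame = f, time_min = (f - 1) * 2.5,
               x = x, y = y, z = z, diameter = 5, parent = parent,
               stringsAsFactors = FALSE)
  d <- rbind(
    row("AB", 1, -10, 0, 0, NA), row("AB", 2, -10, 0.2, 0, NA),
    row("P1", 1, 11, 0, 0, NA), row("P1", 2, 11, -0.2, 0, NA),
    row("ABa", 3, -14, 1, 0, "AB"), row("ABa", 4, -14, 1, 0.2, "AB"),
    row("ABp", 3, -6, -1, 0, "AB"), row("ABp", 4, -6, -1, -0.2, "AB"),
    row("EMS", 3, 6, 2, 0, "P1"), row("EMS", 4, 6, 2.2, 0, "P1"),
    row("P2", 3, 16, -1, 0, "P1"), row("P2", 4, 16, -1, 0, "P1"),
    row("ABal", 5, -16, 1, -2, "ABa"), row("ABar", 5, -12, 1, 2, "ABa"),
    row("ABpl", 5, -8, -1, -2, "ABp"), row("ABpr", 5, -4, -1, 2, "ABp"),
    row("MS", 5, 3, 4, -1, "EMS"), row("MS", 6, 3, 4, -1, "EMS"),
    row("E", 5, 9, 3, 1, "EMS"), row("E", 6, 9, 3, 1, "EMS"))
  embryo_lineage("toy", d, embryo_metadata(group = "control",
                                           relative_AB_size = 60,
                                           outcome = "alive"))
}

# identity embryo frame for tests that bypass axis inference
fx_identity_frame <- function() {
  structure(list(origin = c(0, 0, 0),
                 axes = rbind(AP = c(1, 0, 0), DV = c(0, 1, 0),
                              LR = c(0, 0, 1)),
                 extents = c(AP = 50, DV = 30, LR = 25)),
            class = "embryo_frame")
}

# random-walk track generator for distance-invariant checks
fx_random_tracks <- function(n, len = 8, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    apply(matrix(rnorm(len * 3), len, 3), 2, cumsum))
}
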