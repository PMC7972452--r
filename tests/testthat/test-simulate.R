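test_that("simulation is deterministic given (config, group, seed)", {
  cfg <- fx_sim_config()
  a <- simulate_embryo(cfg, "control", 12)
  b <- simulate_embryo(cfg, "control", 12)
  expect_identical(a$data, b$data)
  expect_identical(a$metadata, b$metadata)
  c2 <- simulate_embryo(cfg, "control", 13)
  expect_false(identical(a$data, c2$data))
})

test_that("AB divides before P1 in every wild-type embryo", {
  cfg <- fx_sim_config()
  for (i in 1:8) {
    e <- simulate_embryo(cfg, "wild_type", 700 + i)
    tr <- cell_tracks(e)
    expect_lt(tr$last_time[tr$cell == "AB"],
              tr$last_time[tr$cell == "P1"])
  }
})

test_that("zero noise collapses a group to identical point sets", {
  cfg <- fx_zero_noise_config()
  a <- simulate_embryo(cfg, "control", 1)
  b <- simulate_embryo(cfg, "control", 999)
  expect_equal(a$data[, c("cell", "frame", "x", "y", "z")],
               b$data[, c("cell", "frame", "x", "y", "z")])
})

test_that("nuclei stay inside the eggshell ellipsoid", {
  cfg <- fx_sim_config(pose_jitter_deg = 0, compression_sd_um = 0)
  e <- simulate_embryo(cfg, "control", 77)
  he <- cfg$eggshell_half_axes
  s <- (e$data$x / he[1])^2 + (e$data$y / he[2])^2 + (e$data$z / he[3])^2
  # positional noise is added after projection; allow a small excess
  expect_lt(stats::quantile(s, 0.999), 1.1)
  expect_lt(max(s), 1.3)
})

test_that("cell-count curves are non-decreasing and clock-ordered", {
  cfg <- fx_sim_config()
  e <- simulate_embryo(cfg, "wild_type", 55)
  cc <- cell_count_curve(e)
  expect_true(all(diff(cc$count) >= 0))
  # at zero timing noise the division order follows the clock table
  z <- fx_zero_noise_config()
  ez <- simulate_embryo(z, "wild_type", 1)
  tr <- cell_tracks(ez)
  div <- tr[tr$n_daughters == 2, ]
  t_of <- function(cl) div$last_time[div$cell == cl]
  expect_lt(t_of("AB"), t_of("P1"))
  expect_lt(t_of("EMS"), t_of("P2"))
  expect_lt(t_of("ABa"), t_of("EMS"))
  expect_lt(t_of("MS"), t_of("E"))
})

test_that("AB-P1 asynchrony shrinks as AB size approaches 50%", {
  cfg <- fx_sim_config()
  asyn <- function(group, seeds) {
    vapply(seeds, function(s) {
      e <- simulate_embryo(cfg, group, s)
      tr <- cell_tracks(e)
      min(tr$first_time[tr$cell %in% c("EMS", "P2")]) -
        min(tr$first_time[tr$cell %in% c("ABa", "ABp")])
    }, numeric(1))
  }
  wt <- asyn("wild_type", 1:8)
  eq <- asyn("equalized_alive", 1:8)
  expect_gt(mean(wt), mean(eq))
})

test_that("planted dead signatures are forced by their parameters", {
  cfg <- fx_sim_config()
  cfg$perturbations$extra_p4_division_prob <- 1
  for (i in 1:3) {
    e <- simulate_embryo(cfg, "equalized_dead", 40 + i)
    p4_cells <- cell_tracks(e)$cell[
      founder_of(cell_tracks(e)$cell)$founder == "P4"]
    expect_gt(length(p4_cells), 2)  # beyond P4 -> Z2, Z3
  }
  # truncated recordings stop around the 26-cell stage
  et <- simulate_embryo(cfg, "control", 99, truncated = TRUE)
  expect_lte(max(cell_count_curve(et)$count), 30)
  expect_gte(max(cell_count_curve(et)$count), 20)
})

test_that("cohort simulation writes consistent outputs", {
  cfg <- fx_sim_config(n_embryos = c(wild_type = 2, control = 2,
                                     equalized_alive = 2,
                                     equalized_dead = 2, inverted = 1))
  out <- withr::local_tempdir()
  res <- simulate_cohort(cfg, out_dir = out)
  expect_length(res$embryos, 9)
  expect_equal(nrow(res$metadata), 9)
  expect_true(all(file.exists(file.path(out, c("lineages.tsv",
                                               "metadata.csv",
                                               "truth.json")))))
  # outcome labels consistent with groups / planted signatures
  expect_true(all(res$metadata$outcome[
    res$metadata$group %in% c("wild_type", "control",
                              "equalized_alive")] == "alive"))
  expect_true(all(res$metadata$outcome[
    res$metadata$group %in% c("equalized_dead", "inverted")] == "dead"))
  # equalized size window respected
  eq <- res$metadata$relative_AB_size[grepl("^equalized",
                                            res$metadata$group)]
  expect_true(all(eq >= 48 & eq <= 53))
  expect_true(all(res$metadata$relative_AB_size[
    res$metadata$group == "inverted"] < 48))
  # lineage files round-trip
  back <- read_native(file.path(out, "lineages.tsv"))
  expect_length(back, 9)
})

test_that("planted truth table tracks the perturbation config", {
  cfg <- fx_sim_config()
  tt <- planted_truth(cfg)
  expect_true(any(tt$cell_pattern == "^Ca$" & tt$feature == "netdis"))
  expect_true(any(tt$cell_pattern == "^ABar" & tt$feature == "pDV"))
  quiet <- cfg
  quiet$perturbations <- perturbation_config(
    p1_clock_scaling = 0, p4_clock_scaling = 0, abar_dv_shift_um = 0,
    ca_netdis_inflation = 1, ms_angle_skew_sd_deg = 0,
    extra_p4_division_prob = 0, ems_skew_prob = 0)
  expect_equal(nrow(planted_truth(quiet)), 0)
})
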