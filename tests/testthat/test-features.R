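test_that("track distances follow Pythagorean arithmetic", {
  P <- rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12))
  d <- track_distances(P)
  expect_equal(unname(d["totdis"]), 17)   # 5 + 12
  expect_equal(unname(d["netdis"]), 13)   # |(3,4,12)|
  # stationary cell
  expect_equal(unname(track_distances(rbind(c(1, 1, 1), c(1, 1, 1)))),
               c(0, 0))
  # straight-line motion: totdis equals netdis
  line <- outer(0:4, c(1, 2, 2))
  dl <- track_distances(line)
  expect_equal(unname(dl["totdis"]), unname(dl["netdis"]))
})

test_that("net displacement never exceeds trajectory length", {
  for (P in fx_random_tracks(200, len = 10, seed = 42)) {
    d <- track_distances(P)
    expect_lte(d["netdis"], d["totdis"] + 1e-12)
  }
})

test_that("angles span [0, 180] with exact symmetry cases", {
  expect_equal(angle_deg(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(angle_deg(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_deg(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_equal(angle_deg(c(2, 0, 0), c(1, 1, 0)), 45)
})

test_that("feature extraction on a hand-built embryo is exact", {
  toy <- fx_toy_embryo()
  fe <- suppressWarnings(extract_features(toy, frame = fx_identity_frame()))
  expect_setequal(names(fe),
                  c("cell", "StartTime", "EndTime", "LifeTime", "pAP",
                    "pLR", "pDV", "totdis", "netdis", "aAP", "aLR",
                    "aDV", "aMean", "pOV"))
  # cells present at recording start have missing StartTime
  expect_true(is.na(fe$StartTime[fe$cell == "AB"]))
  expect_true(is.na(fe$LifeTime[fe$cell == "AB"]))
  # LifeTime = EndTime - StartTime where both exist
  ok <- !is.na(fe$StartTime) & !is.na(fe$EndTime)
  expect_equal(fe$LifeTime[ok], fe$EndTime[ok] - fe$StartTime[ok])
  # undivided cells carry no division time
  expect_true(is.na(fe$EndTime[fe$cell == "P2"]))
  # EMS division vector is MS - E at their first frame:
  # (3,4,-1) - (9,3,1) = (-6,1,-2)
  v <- c(-6, 1, -2)
  expect_equal(fe$aAP[fe$cell == "EMS"], angle_deg(v, c(1, 0, 0)))
  expect_equal(fe$aDV[fe$cell == "EMS"], angle_deg(v, c(0, 1, 0)))
  expect_equal(fe$aLR[fe$cell == "EMS"], angle_deg(v, c(0, 0, 1)))
  # metaphase position is the mother's last tracked frame
  expect_equal(fe$pAP[fe$cell == "EMS"], 6)
  expect_equal(fe$pDV[fe$cell == "EMS"], 2.2)
  # EMS moved (6,2,0) -> (6,2.2,0): totdis = netdis = 0.2
  expect_equal(fe$totdis[fe$cell == "EMS"], 0.2)
  expect_equal(fe$netdis[fe$cell == "EMS"], 0.2)
  # times are on the aligned clock when an alignment is supplied
  al <- structure(list(scale = 2, t_zero_min = 5, correlation = 1),
                  class = "temporal_alignment")
  fe2 <- suppressWarnings(
    extract_features(toy, frame = fx_identity_frame(), alignment = al))
  expect_equal(fe2$LifeTime[ok], 2 * fe$LifeTime[ok])
  expect_equal(fe2$pAP, fe$pAP)     # positions unchanged by time scaling
  expect_equal(fe2$aAP, fe$aAP)
})

test_that("aMean and pOV vanish for an embryo equal to the reference", {
  ref <- fx_zero_reference()
  e <- fx_identical_controls()[[2]]
  fe <- suppressWarnings(
    extract_features(e, alignment = temporal_align(e, ref$curve),
                     reference = ref))
  expect_lt(max(fe$pOV, na.rm = TRUE), 1e-6)
  expect_lt(max(fe$aMean, na.rm = TRUE), 1e-4)
  expect_gt(sum(!is.na(fe$pOV)), 20)
})

test_that("positional deviation curve measures planted offsets", {
  ref <- fx_zero_reference()
  e <- fx_identical_controls()[[1]]
  pd <- positional_deviation_curve(e, ref)
  expect_lt(max(pd$mean_dev, na.rm = TRUE), 1e-6)
  # uniform translation of every nucleus by 2 um along the canonical
  # D-V (imaging y) axis; registration disabled to keep the offset,
  # and the unshifted embryo's frame supplied so the axis origin does
  # not re-centre the cloud
  shifted <- e
  shifted$data$y <- shifted$data$y + 2
  pd2 <- positional_deviation_curve(shifted, ref, frame = infer_axes(e),
                                    register = FALSE)
  dev2 <- pd2$mean_dev[is.finite(pd2$mean_dev)]
  expect_equal(mean(dev2), 2, tolerance = 0.05)
  expect_lt(max(abs(dev2 - 2)), 0.25)
  # with registration the offset is removed again
  pd3 <- positional_deviation_curve(shifted, ref)
  expect_lt(mean(pd3$mean_dev[is.finite(pd3$mean_dev)]), 0.5)
  # embryos not tracked past the 15-cell stage are rejected
  short <- e
  short$data <- short$data[short$data$frame <= 5, ]
  short <- embryo_lineage("short", short$data, e$metadata,
                          validate = FALSE)
  expect_error(positional_deviation_curve(short, ref), "15-cell")
})

test_that("lineage cell counts partition the embryo", {
  e <- fx_controls()[[2]]
  lc <- lineage_cell_counts(e)
  expect_true(all(lc$AB + lc$P1 == lc$total))
  expect_true(all(diff(lc$AB) >= 0))
  expect_true(all(diff(lc$P1) >= 0))
  # AB lineage steps 1 -> 2 -> 4 as AB then ABa/ABp divide
  expect_equal(lc$AB[1], 1)
  expect_true(all(c(2, 4) %in% unique(lc$AB)))
})

test_that("P1 lineage outpaces controls when its clock is accelerated", {
  cfg <- fx_zero_noise_config()
  ctrl <- simulate_embryo(cfg, "control", 1)
  eq <- simulate_embryo(cfg, "equalized_alive", 1)
  t8 <- function(e) {
    lc <- lineage_cell_counts(e)
    min(lc$time[lc$P1 >= 8])
  }
  expect_lt(t8(eq), t8(ctrl))
})

test_that("phenotype flags score planted and constructed defects", {
  ref <- fx_zero_reference()
  e <- fx_identical_controls()[[1]]
  fl <- suppressWarnings(phenotype_flags(e, ref))
  expect_false(fl$ems_skew)
  expect_false(fl$msap_inversion)
  expect_equal(fl$extra_P4_divisions, 0)
  expect_false(isTRUE(fl$t_arrangement))
  expect_gt(fl$ab_p1_asynchrony_min, 0)

  # constructed MSa/MSp left-right inversion: mirror their L-R (here
  # imaging z) coordinates in a zero-noise embryo
  inv <- e
  sel <- inv$data$cell %in% c("MSa", "MSp")
  inv$data$z[sel] <- -inv$data$z[sel]
  fl_inv <- suppressWarnings(phenotype_flags(inv, ref))
  expect_true(fl_inv$msap_inversion)

  # planted EMS skew exceeds the 35 degree threshold
  cfg <- fx_zero_noise_config()
  cfg$perturbations$ems_skew_prob <- 1
  skewed <- simulate_embryo(cfg, "equalized_dead", 5)
  fl_skew <- suppressWarnings(phenotype_flags(skewed, ref))
  expect_true(fl_skew$ems_skew)

  # extra germline division: P4 subtree {P4 -> Z2,Z3; Z2 -> Z2a,Z2p}
  cfg2 <- fx_zero_noise_config()
  cfg2$perturbations$extra_p4_division_prob <- 1
  cfg2$perturbations$ms_angle_skew_sd_deg <- 0
  extra <- simulate_embryo(cfg2, "equalized_dead", 6)
  fl_extra <- suppressWarnings(phenotype_flags(extra, ref))
  expect_equal(fl_extra$extra_P4_divisions, 1)
})

test_that("feature tables have one row per embryo and stage columns", {
  ref <- fx_reference()
  embs <- fx_controls()
  ft4 <- feature_table(embs, ref, stage = 4)
  expect_equal(nrow(ft4), length(embs))
  expect_true(all(paste0("ABa.", c("LifeTime", "pAP", "aMean")) %in%
                    colnames(ft4)))
  expect_false(any(grepl("^MSa\\.", colnames(ft4))))
  ft15 <- feature_table(embs, ref, stage = 15)
  expect_true(any(grepl("^Ca\\.netdis$", colnames(ft15))))
  expect_gt(ncol(ft15), ncol(ft4))
})
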