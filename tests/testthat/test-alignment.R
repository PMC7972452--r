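test_that("Kabsch superposition recovers a planted rigid transform", {
  set.seed(4)
  X <- matrix(rnorm(12), 4, 3)
  R0 <- wormlineage:::random_rotation()
  t0 <- c(2, -1, 3)
  Y <- X %*% R0 + matrix(t0, 4, 3, byrow = TRUE)
  fit <- kabsch(X, Y)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$R, R0, tolerance = 1e-8)
  expect_equal(fit$t, t0, tolerance = 1e-8)
})

test_that("Kabsch matches an independent Procrustes implementation", {
  skip_if_not_installed("vegan")
  set.seed(5)
  for (i in 1:5) {
    X <- matrix(rnorm(18), 6, 3)
    # near-rigid pair, so the optimum is a proper rotation for both
    # implementations (Kabsch excludes reflections)
    Y <- X %*% wormlineage:::random_rotation() +
      matrix(rnorm(18, 0, 0.05), 6, 3) +
      matrix(rnorm(3), 6, 3, byrow = TRUE)
    fit <- kabsch(X, Y)
    ora <- vegan::procrustes(Y, X, scale = FALSE, symmetric = FALSE)
    expect_equal(sqrt(mean(rowSums((fit$Xfit - Y)^2))),
                 sqrt(ora$ss / 6), tolerance = 1e-5)
  }
})

test_that("GPA handles identity and rigid-motion cases exactly", {
  set.seed(6)
  L <- matrix(rnorm(15), 5, 3, dimnames = list(paste0("c", 1:5), NULL))
  one <- gpa_align(list(L))
  expect_equal(one$residual, 0)
  expect_equal(one$mean_shape, L)
  # second embryo is a rigid motion of the first: residual ~ 0
  R0 <- wormlineage:::random_rotation()
  L2 <- L %*% R0 + matrix(c(5, 5, 5), 5, 3, byrow = TRUE)
  rownames(L2) <- rownames(L)
  two <- gpa_align(list(L, L2))
  expect_lt(two$residual, 1e-8)
})

test_that("GPA residual is invariant under rigid pre-transforms", {
  set.seed(7)
  shapes <- lapply(1:4, function(i) {
    M <- matrix(rnorm(24), 8, 3) + i * 0.1
    rownames(M) <- paste0("c", 1:8)
    M
  })
  base <- gpa_align(shapes, tol = 1e-13, max_iter = 2000)
  rot <- shapes
  R0 <- wormlineage:::random_rotation()
  rot[[2]] <- rot[[2]] %*% R0 + matrix(c(-3, 7, 1), 8, 3, byrow = TRUE)
  moved <- gpa_align(rot, tol = 1e-13, max_iter = 2000)
  expect_equal(moved$residual, base$residual, tolerance = 1e-9)
  expect_error(gpa_align(list(shapes[[1]][1:3, ], shapes[[2]][1:3, ])),
               "insufficient-landmark")
})

test_that("axis inference recovers a constructed frame", {
  toy <- fx_toy_embryo()
  fr <- infer_axes(toy)
  # orthonormal right-handed
  expect_equal(unname(fr$axes %*% t(fr$axes)), diag(3),
               tolerance = 1e-9)
  expect_equal(wormlineage:::pracma_cross(fr$axes[1, ], fr$axes[2, ]),
               fr$axes[3, ], tolerance = 1e-9)
  # cloud elongated along x with AB cells anterior (negative side),
  # so A-P comes out as +x; MS sits at +y, so D-V points to +y
  expect_gt(fr$axes[1, 1], 0.95)
  expect_gt(fr$axes[2, 2], 0.5)
})

test_that("axis inference is rotation-equivariant", {
  cfg <- fx_sim_config(pose_jitter_deg = 0)
  e <- simulate_embryo(cfg, "control", 300)
  fr <- infer_axes(e)
  set.seed(8)
  for (i in 1:5) {
    R0 <- wormlineage:::random_rotation()
    er <- e
    xyz <- as.matrix(e$data[, c("x", "y", "z")]) %*% t(R0)
    er$data$x <- xyz[, 1]; er$data$y <- xyz[, 2]; er$data$z <- xyz[, 3]
    fr2 <- infer_axes(er)
    expect_equal(fr2$axes, fr$axes %*% t(R0), tolerance = 1e-6)
    expect_equal(fr2$extents, fr$extents, tolerance = 1e-6)
  }
})

test_that("axis inference rejects degenerate geometry", {
  toy <- fx_toy_embryo()
  no_ms <- toy
  no_ms$data <- no_ms$data[!(no_ms$data$cell %in% c("MS", "E")), ]
  no_ms$data$parent[no_ms$data$cell == "EMS"] <- "P1"
  no_ms <- embryo_lineage("noms", no_ms$data, toy$metadata)
  expect_error(infer_axes(no_ms), "MS-lineage")
})

test_that("temporal alignment recovers dilation factors on the grid", {
  e <- fx_controls()[[1]]
  ref <- mean_count_curve(list(e))
  al <- suppressWarnings(temporal_align(e, ref))
  expect_equal(al$scale, 1, tolerance = 1e-9)
  for (s in c(0.6, 0.8, 1.25, 1.6)) {
    ed <- e
    ed$data$time_min <- ed$data$time_min * s
    als <- suppressWarnings(temporal_align(ed, ref))
    expect_lte(abs(als$scale - 1 / s), 0.001 + 1e-9)
  }
})

test_that("temporal alignment rejects flat growth curves", {
  d <- data.frame(cell = "AB", frame = 1:5, time_min = (0:4) * 2.5,
                  x = 0, y = 0, z = 0, diameter = 5, parent = NA)
  flat <- embryo_lineage("flat", d)
  expect_error(temporal_align(flat, data.frame(time = 0:10, count = 1:11)),
               "alignment error")
})

test_that("reference from identical controls reproduces the input", {
  ref <- fx_zero_reference()
  e <- fx_identical_controls()[[1]]
  al <- temporal_align(e, ref$curve)
  fe <- suppressWarnings(extract_features(e, alignment = al,
                                          reference = ref))
  expect_lt(max(fe$pOV, na.rm = TRUE), 1e-6)
  expect_lt(max(fe$aMean, na.rm = TRUE), 1e-4)  # degrees; fp rotation noise
  # control SDs are zero for identical inputs
  expect_lt(max(ref$feature_sds, na.rm = TRUE), 1e-8)
  expect_equal(ref$n_controls, 3)
  expect_error(reference_cell(ref, "ABalapappa"), "lookup error")
})

test_that("reference construction is order-invariant up to orientation", {
  ctrl <- fx_controls()
  ref1 <- fx_reference()
  ref2 <- build_reference(rev(ctrl))
  # the GPA consensus is defined up to a rigid motion (set by the
  # initial embryo), so compare rigid invariants: residual and the
  # inter-cell distance structure of the mean shape
  expect_equal(ref1$gpa_residual, ref2$gpa_residual, tolerance = 1e-6)
  cells <- intersect(ref1$cells, ref2$cells)
  ok <- cells[stats::complete.cases(ref1$mean_position[cells, ]) &
                stats::complete.cases(ref2$mean_position[cells, ])]
  d1 <- dist(ref1$mean_position[ok, ])
  d2 <- dist(ref2$mean_position[ok, ])
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-4)
})
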