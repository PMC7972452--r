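# Temporal and spatial embryo alignment and the control reference model.
#
# Embryos are aligned in time by scaling their cell-count growth curve to
# a reference curve (maximum Pearson correlation over a scale grid) with
# time zero at the ABa division, and in space by inferring the A-P / D-V /
# L-R frame from the nuclear point cloud. A reference model is built from
# control embryos by Generalized Procrustes Analysis of per-cell metaphase
# landmarks, storing mean positions, mean division vectors and 1-minute
# mean trajectories.

#' Cell-count growth curve of an embryo
#'
#' @param embryo an `embryo_lineage`.
#' @return data.frame with columns `time` (minutes, raw recording clock)
#'   and `count` (number of tracked nuclei at that frame).
#' @export
cell_count_curve <- function(embryo) {
  d <- embryo$data
  agg <- stats::aggregate(d$cell, by = list(time = d$time_min), FUN = length)
  names(agg)[2] <- "count"
  agg[order(agg$time), ]
}

# division time of a cell: operationalized as its last tracked frame
# (metaphase proxy); NA if the cell never divides in the record
.division_time <- function(embryo, cell) {
  tr <- cell_tracks(embryo)
  row <- tr[tr$cell == cell, ]
  if (!nrow(row) || row$n_daughters == 0L) return(NA_real_)
  row$last_time
}

#' Average centered cell-count curve of a set of embryos
#'
#' Each embryo's curve is shifted so that time zero is its ABa division
#' and linearly interpolated to a shared 1-minute grid; the pointwise mean
#' over embryos defines the reference pace of development.
#'
#' @param embryos list of `embryo_lineage`.
#' @return data.frame `time`, `count`.
#' @export
mean_count_curve <- function(embryos) {
  centered <- lapply(embryos, function(e) {
    t0 <- .division_time(e, "ABa")
    if (is.na(t0)) stop("alignment error: ABa division not observed in '",
                        e$embryo_id, "'", call. = FALSE)
    cc <- cell_count_curve(e)
    cc$time <- cc$time - t0
    cc
  })
  lo <- max(vapply(centered, function(cc) min(cc$time), numeric(1)))
  hi <- min(vapply(centered, function(cc) max(cc$time), numeric(1)))
  grid <- seq(floor(lo), ceiling(hi), by = 1)
  vals <- vapply(centered, function(cc)
    stats::approx(cc$time, cc$count, xout = grid, rule = 2)$y,
    numeric(length(grid)))
  data.frame(time = grid, count = rowMeans(as.matrix(vals)))
}

#' Temporal alignment of an embryo to a reference growth curve
#'
#' Finds the dimensionless scale factor maximizing the Pearson correlation
#' between the embryo's linearly interpolated, ABa-centered cell-count
#' curve and the reference curve, searched on a fixed grid; aligned time
#' is `(raw_time - t_zero) * scale` with `t_zero` the ABa division.
#'
#' @param embryo an `embryo_lineage` with at least 8 observed divisions.
#' @param reference_curve data.frame `time`, `count` on the centered
#'   clock, as from [mean_count_curve()].
#' @param scale_grid candidate scale factors.
#' @return object of class `temporal_alignment`: list with `scale`,
#'   `t_zero_min` and the achieved `correlation`.
#' @export
temporal_align <- function(embryo, reference_curve,
                           scale_grid = seq(0.5, 2, by = 0.001)) {
  tr <- cell_tracks(embryo)
  n_div <- sum(tr$n_daughters == 2L)
  if (n_div == 0L)
    stop("alignment error: embryo '", embryo$embryo_id,
         "' shows no divisions (flat growth curve)", call. = FALSE)
  if (n_div < 8L)
    warning("fewer than 8 divisions observed; scale estimate may be poor")
  t0 <- .division_time(embryo, "ABa")
  if (is.na(t0))
    stop("alignment error: ABa division not observed in '",
         embryo$embryo_id, "'", call. = FALSE)
  cc <- cell_count_curve(embryo)
  ct <- cc$time - t0
  best <- c(scale = NA_real_, cor = -Inf)
  for (s in scale_grid) {
    st <- ct * s
    lo <- max(min(reference_curve$time), min(st))
    hi <- min(max(reference_curve$time), max(st))
    if (hi - lo < 10) next
    grid <- seq(lo, hi, by = 1)
    ref_v <- stats::approx(reference_curve$time, reference_curve$count,
                           xout = grid)$y
    emb_v <- stats::approx(st, cc$count, xout = grid)$y
    if (stats::sd(ref_v) == 0 || stats::sd(emb_v) == 0) next
    r <- stats::cor(ref_v, emb_v)
    if (r > best["cor"] + 1e-12 ||
        (abs(r - best["cor"]) <= 1e-12 &&
         abs(s - 1) < abs(best["scale"] - 1))) {
      best <- c(scale = s, cor = r)
    }
  }
  if (!is.finite(best["cor"]))
    stop("alignment error: no usable curve overlap with the reference",
         call. = FALSE)
  structure(list(scale = unname(best["scale"]), t_zero_min = t0,
                 correlation = unname(best["cor"])),
            class = "temporal_alignment")
}

#' Aligned developmental time
#' @param time_min raw recording times (minutes).
#' @param alignment a `temporal_alignment`.
#' @return `(time_min - t_zero) * scale`.
#' @export
aligned_time <- function(time_min, alignment) {
  (time_min - alignment$t_zero_min) * alignment$scale
}

#' Infer the embryonic A-P / D-V / L-R frame
#'
#' The A-P axis is the first principal component of all nuclear positions
#' within the first `n_frames` recorded frames; the D-V axis is the
#' component of (MS-lineage centroid - embryo centre) orthogonal to A-P;
#' L-R completes a right-handed frame. Signs: A-P is oriented so the
#' AB-lineage centroid lies on the negative (anterior) side, D-V so the
#' ventral (MS) side is positive. Axes are computed from centred raw
#' coordinates, which keeps the frame strictly rotation-equivariant;
#' per-axis extent normalization is applied afterwards, in the embryo
#' frame, when normalized coordinates are requested.
#'
#' @param embryo an `embryo_lineage`.
#' @param n_frames number of initial recorded frames used (default 100).
#' @return object of class `embryo_frame`: list with `origin` (centre),
#'   `axes` (3x3 orthonormal, rows = A-P, D-V, L-R) and `extents` (full
#'   embryo extent along each inferred axis, micrometres).
#' @export
infer_axes <- function(embryo, n_frames = 100L) {
  d <- embryo$data
  f0 <- min(d$frame)
  win <- d[d$frame < f0 + n_frames, ]
  if (length(unique(win$cell)) < 4L)
    stop("axis error: fewer than 4 cells tracked in the axis window",
         call. = FALSE)
  X <- as.matrix(win[, c("x", "y", "z")])
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  pc <- stats::prcomp(Xc, center = FALSE)
  if (pc$sdev[1] < 1.2 * pc$sdev[2])
    warning("low anisotropy: A-P axis is ill-conditioned")
  ap <- as.numeric(pc$rotation[, 1])
  super <- founder_of(unique(win$cell))$super_lineage
  ab_cells <- unique(win$cell)[super == "AB"]
  if (length(ab_cells)) {
    ab_centroid <- colMeans(win[win$cell %in% ab_cells, c("x", "y", "z")])
    if (sum((ab_centroid - center) * ap) > 0) ap <- -ap
  }
  ms_cells <- unique(win$cell)[founder_of(unique(win$cell))$founder == "MS"]
  if (!length(ms_cells))
    stop("axis error: no MS-lineage cells tracked; D-V axis undefined",
         call. = FALSE)
  ms_centroid <- colMeans(win[win$cell %in% ms_cells, c("x", "y", "z"),
                              drop = FALSE])
  v <- ms_centroid - center
  dv <- v - sum(v * ap) * ap
  if (sqrt(sum(dv^2)) < 1e-9)
    stop("axis error: MS centroid collinear with A-P axis", call. = FALSE)
  dv <- as.numeric(unit_vector(dv))
  lr <- pracma_cross(ap, dv)
  axes <- rbind(AP = ap, DV = dv, LR = lr)
  dimnames(axes) <- list(c("AP", "DV", "LR"), NULL)
  proj <- Xc %*% t(axes)
  extents <- apply(proj, 2, function(u) diff(range(u)))
  names(extents) <- c("AP", "DV", "LR")
  structure(list(origin = unname(center), axes = axes,
                 extents = extents),
            class = "embryo_frame")
}

#' Embryo-frame coordinates of tracked nuclei
#'
#' Transforms imaging coordinates into the inferred A-P/D-V/L-R frame.
#' With `normalize = TRUE`, coordinates are divided by the embryo's own
#' half-extents and rescaled by `ref_extents` (typically the control-mean
#' extents), yielding micrometre-equivalent normalized coordinates.
#'
#' @param embryo an `embryo_lineage`.
#' @param frame an `embryo_frame` from [infer_axes()].
#' @param normalize normalize per-axis by embryo extents.
#' @param ref_extents full extents used to rescale normalized coordinates
#'   (defaults to the embryo's own, i.e. no rescaling).
#' @return data.frame `cell`, `frame`, `time_min`, `ap`, `dv`, `lr`.
#' @export
frame_coordinates <- function(embryo, frame, normalize = FALSE,
                              ref_extents = NULL) {
  d <- embryo$data
  X <- sweep(as.matrix(d[, c("x", "y", "z")]), 2, frame$origin)
  P <- X %*% t(frame$axes)
  if (normalize) {
    ref <- ref_extents %||% frame$extents
    P <- sweep(P, 2, frame$extents / 2, "/")
    P <- sweep(P, 2, ref / 2, "*")
  }
  data.frame(cell = d$cell, frame = d$frame, time_min = d$time_min,
             ap = P[, 1], dv = P[, 2], lr = P[, 3],
             stringsAsFactors = FALSE)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation `R` and translation that superimpose landmark rows
#' of `X` onto `Y` minimizing the sum of squared distances; optionally
#' with isotropic scaling (classical Procrustes).
#'
#' @param X,Y n x 3 matrices of corresponding landmarks.
#' @param scale allow isotropic scaling.
#' @return list with `R` (3x3 rotation), `s` (scale), `t` (translation);
#'   the fitted configuration is `s * X %*% R + t` (row convention), also
#'   returned as `Xfit`, with `rmsd`.
#' @export
kabsch <- function(X, Y, scale = FALSE) {
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 3, ncol(Y) == 3)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- t(Xc) %*% Yc
  sv <- svd(H)
  dsign <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, dsign))
  R <- sv$u %*% D %*% t(sv$v)
  s <- if (scale) sum(diag(D) * sv$d) / sum(Xc^2) else 1
  t_vec <- cy - s * (cx %*% R)[1, ]
  Xfit <- s * X %*% R + matrix(t_vec, nrow(X), 3, byrow = TRUE)
  list(R = R, s = s, t = t_vec, Xfit = Xfit,
       rmsd = sqrt(mean(rowSums((Xfit - Y)^2))))
}

#' Generalized Procrustes Analysis of named landmark sets
#'
#' Iteratively superimposes each embryo's landmark configuration onto the
#' running mean shape by least-squares rotation and translation (no
#' scaling by default, because extent normalization already removes
#' size), recomputing the mean until it changes by less than `tol` or
#' `max_iter` iterations. Landmarks are matched by name; cells missing
#' from an embryo are dropped pairwise.
#'
#' @param landmarks list of matrices (rows = cells, rownames = cell
#'   names, 3 columns).
#' @param scale use classical scaling GPA.
#' @param tol convergence tolerance on the mean residual.
#' @param max_iter iteration cap.
#' @return list with `aligned` (transformed landmark list), `mean_shape`
#'   (matrix over the union of cells), `residual` (mean RMSD), and
#'   `transforms` (per embryo `R`, `s`, `t`).
#' @export
gpa_align <- function(landmarks, scale = FALSE, tol = 1e-6,
                      max_iter = 100L) {
  stopifnot(length(landmarks) >= 1L)
  landmarks <- lapply(landmarks, function(L) {
    L[stats::complete.cases(L), , drop = FALSE]
  })
  if (length(landmarks) == 1L) {
    return(list(aligned = landmarks, mean_shape = landmarks[[1]],
                residual = 0,
                transforms = list(list(R = diag(3), s = 1, t = c(0, 0, 0)))))
  }
  all_cells <- Reduce(union, lapply(landmarks, rownames))
  mean_over <- function(lst) {
    M <- matrix(NA_real_, length(all_cells), 3,
                dimnames = list(all_cells, NULL))
    for (cell in all_cells) {
      rows <- lapply(lst, function(L)
        if (cell %in% rownames(L)) L[cell, ] else NULL)
      rows <- do.call(rbind, rows)
      if (!is.null(rows)) M[cell, ] <- colMeans(rows)
    }
    M
  }
  aligned <- landmarks
  mean_shape <- mean_over(aligned)
  transforms <- rep(list(list(R = diag(3), s = 1, t = c(0, 0, 0))),
                    length(landmarks))
  res_prev <- Inf
  for (it in seq_len(max_iter)) {
    resids <- numeric(length(landmarks))
    for (i in seq_along(landmarks)) {
      shared <- intersect(rownames(landmarks[[i]]),
                          all_cells[stats::complete.cases(mean_shape)])
      if (length(shared) < 4L)
        stop("insufficient-landmark error: embryo ", i, " shares only ",
             length(shared), " landmarks with the consensus", call. = FALSE)
      fit <- kabsch(landmarks[[i]][shared, , drop = FALSE],
                    mean_shape[shared, , drop = FALSE], scale = scale)
      aligned[[i]] <- fit$s * landmarks[[i]] %*% fit$R +
        matrix(fit$t, nrow(landmarks[[i]]), 3, byrow = TRUE)
      transforms[[i]] <- fit[c("R", "s", "t")]
      resids[i] <- fit$rmsd
    }
    mean_shape <- mean_over(aligned)
    res <- mean(resids)
    if (abs(res_prev - res) < tol) break
    res_prev <- res
  }
  list(aligned = aligned, mean_shape = mean_shape, residual = res,
       transforms = transforms)
}

# per-cell metaphase landmark matrix in embryo-frame coordinates:
# each cell contributes its position at its last tracked frame
.metaphase_landmarks <- function(coords) {
  by_cell <- split(coords, coords$cell)
  M <- t(vapply(by_cell, function(sub) {
    i <- which.max(sub$frame)
    c(sub$ap[i], sub$dv[i], sub$lr[i])
  }, numeric(3)))
  M
}

# division vector of each divided cell: first daughter (a/l/d or the
# first P-lineage name) minus sister, at the daughters' first common
# frame, in the coordinate columns of `coords`
.division_vectors <- function(embryo, coords) {
  tr <- cell_tracks(embryo)
  mothers <- tr$cell[tr$n_daughters == 2L]
  out <- matrix(NA_real_, length(mothers), 3,
                dimnames = list(mothers, NULL))
  for (m in mothers) {
    kids <- tr$cell[!is.na(tr$parent) & tr$parent == m]
    if (length(kids) != 2L) next
    canon <- tryCatch(sulston_daughters(m), error = function(e) NULL)
    first <- if (!is.null(canon) && canon[1] %in% kids) canon[1]
             else sort(kids)[1]
    second <- setdiff(kids, first)
    f1 <- coords[coords$cell == first, ]
    f2 <- coords[coords$cell == second, ]
    common <- intersect(f1$frame, f2$frame)
    if (!length(common)) next
    fr <- min(common)
    v <- c(f1$ap[f1$frame == fr] - f2$ap[f2$frame == fr],
           f1$dv[f1$frame == fr] - f2$dv[f2$frame == fr],
           f1$lr[f1$frame == fr] - f2$lr[f2$frame == fr])
    out[m, ] <- v
  }
  out
}

#' Build the control reference model
#'
#' Aligns control embryos in time (growth-curve scaling, time zero at ABa
#' division) and space (inferred axes, extent normalization to the
#' cohort-mean extents, then GPA of per-cell metaphase landmarks), and
#' stores per cell: the mean metaphase position, the mean unit division
#' vector, and the 1-minute mean trajectory; per cell and feature, the
#' control mean and sample SD.
#'
#' @param control_embryos list of >= 2 temporally alignable
#'   `embryo_lineage` objects.
#' @param scale_gpa use scaling GPA (default rigid only).
#' @return object of class `reference_model`.
#' @export
build_reference <- function(control_embryos, scale_gpa = FALSE) {
  stopifnot(length(control_embryos) >= 1L)
  curve <- mean_count_curve(control_embryos)
  aligns <- lapply(control_embryos, temporal_align, reference_curve = curve)
  frames <- lapply(control_embryos, infer_axes)
  mean_extents <- rowMeans(vapply(frames, function(f) f$extents,
                                  numeric(3)))
  names(mean_extents) <- c("AP", "DV", "LR")
  coords <- mapply(function(e, f, a) {
    cc <- frame_coordinates(e, f, normalize = TRUE,
                            ref_extents = mean_extents)
    cc$time_aligned <- aligned_time(cc$time_min, a)
    cc
  }, control_embryos, frames, aligns, SIMPLIFY = FALSE)

  landmarks <- lapply(coords, .metaphase_landmarks)
  gpa <- gpa_align(landmarks, scale = scale_gpa)

  # apply each embryo's GPA transform to its full trajectory
  coords_gpa <- mapply(function(cc, tf) {
    P <- as.matrix(cc[, c("ap", "dv", "lr")])
    P <- tf$s * P %*% tf$R + matrix(tf$t, nrow(P), 3, byrow = TRUE)
    cc$ap <- P[, 1]; cc$dv <- P[, 2]; cc$lr <- P[, 3]
    cc
  }, coords, gpa$transforms, SIMPLIFY = FALSE)

  # mean unit division vectors (rotated by the same transforms)
  divvec_list <- mapply(function(e, cc) .division_vectors(e, cc),
                        control_embryos, coords_gpa, SIMPLIFY = FALSE)
  all_cells <- rownames(gpa$mean_shape)
  mean_divvec <- matrix(NA_real_, length(all_cells), 3,
                        dimnames = list(all_cells, NULL))
  for (cell in all_cells) {
    vs <- lapply(divvec_list, function(M)
      if (cell %in% rownames(M) && all(is.finite(M[cell, ])))
        unit_vector(M[cell, ]) else NULL)
    vs <- do.call(rbind, vs)
    if (!is.null(vs) && nrow(vs))
      mean_divvec[cell, ] <- unit_vector(colMeans(vs))
  }

  # per-minute mean trajectories on the aligned clock
  traj <- list()
  for (cell in all_cells) {
    segs <- lapply(coords_gpa, function(cc) cc[cc$cell == cell, ])
    segs <- segs[vapply(segs, nrow, integer(1)) > 0]
    if (!length(segs)) next
    lo <- floor(min(vapply(segs, function(s) min(s$time_aligned),
                           numeric(1))))
    hi <- ceiling(max(vapply(segs, function(s) max(s$time_aligned),
                             numeric(1))))
    grid <- seq(lo, hi, by = 1)
    acc <- matrix(0, length(grid), 3)
    cnt <- numeric(length(grid))
    for (s in segs) {
      if (nrow(s) == 1L) {
        j <- which.min(abs(grid - s$time_aligned))
        acc[j, ] <- acc[j, ] + c(s$ap, s$dv, s$lr)
        cnt[j] <- cnt[j] + 1
        next
      }
      ok <- grid >= min(s$time_aligned) & grid <= max(s$time_aligned)
      if (!any(ok)) next
      gx <- grid[ok]
      acc[ok, 1] <- acc[ok, 1] + stats::approx(s$time_aligned, s$ap, gx)$y
      acc[ok, 2] <- acc[ok, 2] + stats::approx(s$time_aligned, s$dv, gx)$y
      acc[ok, 3] <- acc[ok, 3] + stats::approx(s$time_aligned, s$lr, gx)$y
      cnt[ok] <- cnt[ok] + 1
    }
    keep <- cnt > 0
    traj[[cell]] <- data.frame(time = grid[keep],
                               ap = acc[keep, 1] / cnt[keep],
                               dv = acc[keep, 2] / cnt[keep],
                               lr = acc[keep, 3] / cnt[keep])
  }

  # control mean and sample SD of the alignment-free features per cell
  feats <- mapply(function(e, f, a)
    suppressWarnings(extract_features(e, f, a)),
    control_embryos, frames, aligns, SIMPLIFY = FALSE)
  feat_names <- setdiff(.feature_names, c("aMean", "pOV"))
  feature_means <- matrix(NA_real_, length(all_cells), length(feat_names),
                          dimnames = list(all_cells, feat_names))
  feature_sds <- feature_means
  for (cell in all_cells) {
    vals <- do.call(rbind, lapply(feats, function(fe) {
      r <- fe[fe$cell == cell, feat_names]
      if (nrow(r)) as.numeric(r[1, ]) else NULL
    }))
    if (is.null(vals)) next
    feature_means[cell, ] <- colMeans(vals, na.rm = TRUE)
    if (nrow(vals) > 1L)
      feature_sds[cell, ] <- apply(vals, 2, stats::sd, na.rm = TRUE)
  }

  structure(list(cells = all_cells,
                 mean_position = gpa$mean_shape,
                 mean_division_vector = mean_divvec,
                 trajectories = traj,
                 feature_means = feature_means,
                 feature_sds = feature_sds,
                 extents = mean_extents,
                 curve = curve,
                 gpa_residual = gpa$residual,
                 n_controls = length(control_embryos)),
            class = "reference_model")
}

#' Query the reference model for a cell
#' @param reference a `reference_model`.
#' @param cell cell name.
#' @return list with `position`, `division_vector`, `trajectory`.
#' @export
reference_cell <- function(reference, cell) {
  if (!cell %in% reference$cells ||
      !any(is.finite(reference$mean_position[cell, ])))
    stop("lookup error: cell '", cell,
         "' is absent from all control embryos", call. = FALSE)
  list(position = reference$mean_position[cell, ],
       division_vector = reference$mean_division_vector[cell, ],
       trajectory = reference$trajectories[[cell]])
}

#' Register an embryo's landmark coordinates onto the reference model
#'
#' Rigid superposition (rotation + translation) of the embryo's per-cell
#' metaphase landmarks onto the reference mean positions, matched by
#' name; returns the transform applied to the supplied coordinate table.
#'
#' @param coords coordinate table from [frame_coordinates()].
#' @param reference a `reference_model`.
#' @return list `coords` (transformed), `transform`, `n_shared`.
#' @export
register_to_reference <- function(coords, reference) {
  L <- .metaphase_landmarks(coords)
  shared <- intersect(rownames(L),
                      reference$cells[stats::complete.cases(
                        reference$mean_position)])
  if (length(shared) < 4L)
    stop("insufficient-landmark error: only ", length(shared),
         " cells shared with the reference", call. = FALSE)
  fit <- kabsch(L[shared, , drop = FALSE],
                reference$mean_position[shared, , drop = FALSE])
  P <- as.matrix(coords[, c("ap", "dv", "lr")])
  P <- P %*% fit$R + matrix(fit$t, nrow(P), 3, byrow = TRUE)
  coords$ap <- P[, 1]; coords$dv <- P[, 2]; coords$lr <- P[, 3]
  list(coords = coords, transform = fit[c("R", "s", "t")],
       n_shared = length(shared))
}
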