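# Per-cell feature extraction from aligned embryos.
#
# Thirteen features per cell: StartTime, EndTime, LifeTime (aligned
# minutes); pAP, pLR, pDV (metaphase position along the embryonic axes);
# totdis, netdis (trajectory length and net displacement, micrometres);
# aAP, aLR, aDV (division angles against the axes, degrees); aMean
# (angle to the reference division vector) and pOV (distance to the
# reference metaphase position). Metaphase is operationalized as the
# mother's last tracked frame and anaphase onset as the daughters' first
# frame; the 2.5-minute sampling makes finer staging impossible.

.feature_names <- c("StartTime", "EndTime", "LifeTime", "pAP", "pLR",
                    "pDV", "totdis", "netdis", "aAP", "aLR", "aDV",
                    "aMean", "pOV")

# cumulative feature universe: all cells attributed to stages up to
# `stage` ("all" = through the 28-cell cohort)
.stage_cells <- function(stage) {
  stages <- c(4, 8, 15, 28)
  upto <- if (identical(stage, "all")) stages else stages[stages <= stage]
  unique(unlist(lapply(upto, generation_cohort)))
}

#' Trajectory length and net displacement of a track
#'
#' @param P matrix of successive 3D positions (rows ordered in time).
#' @return named vector: `totdis` (sum of frame-to-frame displacements)
#'   and `netdis` (birth-to-end Euclidean distance).
#' @export
track_distances <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) < 2L) return(c(totdis = 0, netdis = 0))
  steps <- sqrt(rowSums(diff(P)^2))
  c(totdis = sum(steps),
    netdis = sqrt(sum((P[nrow(P), ] - P[1, ])^2)))
}

#' Extract the 13 per-cell features of one embryo
#'
#' Positions are expressed in the inferred embryo frame; when a reference
#' model is supplied, coordinates are extent-normalized to the reference
#' mean extents and rigidly registered onto the reference mean shape, and
#' the comparison features `aMean` (angle between the observed division
#' vector and the reference division vector) and `pOV` (Euclidean
#' distance between the metaphase position and the reference mean
#' position) are filled in; otherwise they are `NA`. Times are reported
#' on the aligned clock when `alignment` is given. `StartTime` is `NA`
#' for cells already present at recording start; `EndTime`/`LifeTime`
#' are `NA` for cells whose division was not observed.
#'
#' @param embryo an `embryo_lineage`.
#' @param frame an `embryo_frame`; inferred with [infer_axes()] if `NULL`.
#' @param alignment optional `temporal_alignment`.
#' @param reference optional `reference_model`.
#' @return data.frame with a `cell` column and the 13 feature columns.
#' @export
extract_features <- function(embryo, frame = NULL, alignment = NULL,
                             reference = NULL) {
  if (is.null(frame)) frame <- infer_axes(embryo)
  coords <- frame_coordinates(
    embryo, frame, normalize = !is.null(reference),
    ref_extents = if (!is.null(reference)) reference$extents)
  if (!is.null(reference))
    coords <- register_to_reference(coords, reference)$coords
  tmap <- if (is.null(alignment)) function(t) t
          else function(t) aligned_time(t, alignment)

  tr <- cell_tracks(embryo)
  first_recorded <- min(embryo$data$frame)
  divvec <- .division_vectors(embryo, coords)

  div_ok <- if (nrow(divvec)) rownames(divvec)[
    rowSums(is.finite(divvec)) == 3L] else character(0)
  one_missing <- tr$cell[tr$n_daughters == 2L & !(tr$cell %in% div_ok)]
  if (length(one_missing))
    warning("division vector missing for: ",
            paste(one_missing, collapse = ", "))

  rows <- lapply(seq_len(nrow(tr)), function(i) {
    cell <- tr$cell[i]
    sub <- coords[coords$cell == cell, ]
    sub <- sub[order(sub$frame), ]
    P <- as.matrix(sub[, c("ap", "dv", "lr")])
    divided <- tr$n_daughters[i] == 2L
    start <- if (tr$first_frame[i] == first_recorded) NA_real_
             else tmap(tr$first_time[i])
    end <- if (divided) tmap(tr$last_time[i]) else NA_real_
    meta <- P[nrow(P), ]      # metaphase proxy: last tracked frame
    dist2 <- track_distances(P)
    v <- if (cell %in% rownames(divvec)) divvec[cell, ] else rep(NA_real_, 3)
    has_v <- all(is.finite(v))
    aAP <- if (has_v) angle_deg(v, c(1, 0, 0)) else NA_real_
    aDV <- if (has_v) angle_deg(v, c(0, 1, 0)) else NA_real_
    aLR <- if (has_v) angle_deg(v, c(0, 0, 1)) else NA_real_
    aMean <- NA_real_; pOV <- NA_real_
    if (!is.null(reference) && cell %in% reference$cells &&
        all(is.finite(reference$mean_position[cell, ]))) {
      pOV <- sqrt(sum((meta - reference$mean_position[cell, ])^2))
      rv <- reference$mean_division_vector[cell, ]
      if (has_v && all(is.finite(rv))) aMean <- angle_deg(v, rv)
    }
    data.frame(cell = cell, StartTime = start, EndTime = end,
               LifeTime = end - start, pAP = meta[1], pLR = meta[3],
               pDV = meta[2], totdis = unname(dist2["totdis"]),
               netdis = unname(dist2["netdis"]), aAP = aAP, aLR = aLR,
               aDV = aDV, aMean = aMean, pOV = pOV,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean positional deviation from the reference over time
#'
#' At each 1-minute gridpoint of the aligned clock, each live cell's
#' interpolated position is compared with the reference trajectory of the
#' same cell; the mean deviation is the sum of the Euclidean distances
#' divided by the number of cells scored at that time. Cells missing from
#' the reference are skipped and excluded from the denominator.
#'
#' @param embryo an `embryo_lineage` tracked past the 15-cell stage.
#' @param reference a `reference_model`.
#' @param frame optional `embryo_frame`.
#' @param alignment optional `temporal_alignment` (defaults to scale 1,
#'   time zero at ABa division).
#' @param register rigidly register the embryo onto the reference mean
#'   shape first (default); disable to measure raw embryo-frame offsets,
#'   e.g. a uniform translation.
#' @return data.frame `time`, `mean_dev`, `sd_dev`, `n_cells`.
#' @export
positional_deviation_curve <- function(embryo, reference, frame = NULL,
                                       alignment = NULL, register = TRUE) {
  cc <- cell_count_curve(embryo)
  if (max(cc$count) < 15)
    stop("embryo not lineaged past the 15-cell stage", call. = FALSE)
  if (is.null(frame)) frame <- infer_axes(embryo)
  if (is.null(alignment))
    alignment <- structure(list(scale = 1,
                                t_zero_min = .division_time(embryo, "ABa"),
                                correlation = NA_real_),
                           class = "temporal_alignment")
  coords <- frame_coordinates(embryo, frame, normalize = TRUE,
                              ref_extents = reference$extents)
  if (register)
    coords <- register_to_reference(coords, reference)$coords
  coords$ta <- aligned_time(coords$time_min, alignment)

  grid <- seq(floor(min(coords$ta)), ceiling(max(coords$ta)), by = 1)
  by_cell <- split(coords, coords$cell)
  by_cell <- by_cell[names(by_cell) %in% names(reference$trajectories)]
  res <- t(vapply(grid, function(t) {
    devs <- unlist(lapply(by_cell, function(sub) {
      if (t < min(sub$ta) || t > max(sub$ta)) return(NULL)
      p <- if (nrow(sub) == 1L) c(sub$ap, sub$dv, sub$lr)
           else c(stats::approx(sub$ta, sub$ap, t)$y,
                  stats::approx(sub$ta, sub$dv, t)$y,
                  stats::approx(sub$ta, sub$lr, t)$y)
      tr <- reference$trajectories[[sub$cell[1]]]
      if (t < min(tr$time) || t > max(tr$time)) return(NULL)
      q <- if (nrow(tr) == 1L) c(tr$ap, tr$dv, tr$lr)
           else c(stats::approx(tr$time, tr$ap, t)$y,
                  stats::approx(tr$time, tr$dv, t)$y,
                  stats::approx(tr$time, tr$lr, t)$y)
      sqrt(sum((p - q)^2))
    }))
    if (is.null(devs) || !length(devs))
      return(c(NA_real_, NA_real_, 0))
    c(mean(devs), stats::sd(devs), length(devs))
  }, numeric(3)))
  data.frame(time = grid, mean_dev = res[, 1], sd_dev = res[, 2],
             n_cells = res[, 3])
}

#' Live-cell counts per super-lineage
#'
#' Step curves of the number of tracked AB-lineage and P1-lineage cells
#' over time (aligned clock when an alignment is supplied).
#'
#' @param embryo an `embryo_lineage`.
#' @param alignment optional `temporal_alignment`.
#' @return data.frame `time`, `AB`, `P1`, `total`.
#' @export
lineage_cell_counts <- function(embryo, alignment = NULL) {
  d <- embryo$data
  super <- founder_of(unique(d$cell))
  sl <- super$super_lineage[match(d$cell, super$cell)]
  times <- sort(unique(d$time_min))
  ab <- vapply(times, function(t)
    length(unique(d$cell[d$time_min == t & sl == "AB"])), numeric(1))
  p1 <- vapply(times, function(t)
    length(unique(d$cell[d$time_min == t & sl != "AB"])), numeric(1))
  tt <- if (is.null(alignment)) times else aligned_time(times, alignment)
  data.frame(time = tt, AB = ab, P1 = p1, total = ab + p1)
}

#' Qualitative phenotype flags of one embryo
#'
#' Scores the discrete phenotypes: EMS division skew greater than 35
#' degrees at anaphase onset (angle to the reference EMS division
#' vector); left-right inversion of MSa/MSp prior to their division
#' (both L-R coordinates sign-flipped relative to the reference); number
#' of divisions in the P4 (germline) subtree beyond the normal single
#' division; AB-P1 division asynchrony in minutes (anaphase onsets,
#' aligned clock); and a T-shaped 4-cell arrangement proxy (AB daughter
#' axis nearly parallel to A-P while P2 is unusually far from ABp).
#'
#' @param embryo an `embryo_lineage`.
#' @param reference a `reference_model` (needed for `ems_skew` and
#'   `msap_inversion`; they are `NA` without it).
#' @param frame optional `embryo_frame`.
#' @param alignment optional `temporal_alignment`.
#' @param skew_threshold_deg EMS skew cutoff (default 35 degrees).
#' @return list of class `phenotype_flags`.
#' @export
phenotype_flags <- function(embryo, reference = NULL, frame = NULL,
                            alignment = NULL, skew_threshold_deg = 35) {
  if (is.null(frame)) frame <- infer_axes(embryo)
  feats <- extract_features(embryo, frame, alignment, reference)
  tr <- cell_tracks(embryo)

  ems_skew <- if ("EMS" %in% feats$cell)
    isTRUE(feats$aMean[feats$cell == "EMS"] > skew_threshold_deg)
  else NA

  msap_inversion <- NA
  if (!is.null(reference) && all(c("MSa", "MSp") %in% feats$cell) &&
      all(c("MSa", "MSp") %in% reference$cells)) {
    obs <- feats$pLR[match(c("MSa", "MSp"), feats$cell)]
    ref <- reference$mean_position[c("MSa", "MSp"), 3]
    msap_inversion <- all(is.finite(obs)) && all(is.finite(ref)) &&
      all(abs(ref) > 0.5) && all(sign(obs) == -sign(ref))
  }

  p4_sub <- founder_of(tr$cell)
  p4_divs <- sum(tr$n_daughters == 2L & p4_sub$founder == "P4")
  extra_p4 <- max(0L, p4_divs - 1L)

  asyn <- NA_real_
  ab_d <- tr$first_time[match(c("ABa", "ABp"), tr$cell)]
  p1_d <- tr$first_time[match(c("EMS", "P2"), tr$cell)]
  if (any(is.finite(ab_d)) && any(is.finite(p1_d))) {
    asyn <- min(p1_d, na.rm = TRUE) - min(ab_d, na.rm = TRUE)
    if (!is.null(alignment)) asyn <- asyn * alignment$scale
  }

  t_arr <- NA
  four <- c("ABa", "ABp", "EMS", "P2")
  if (all(four %in% embryo$data$cell)) {
    co <- frame_coordinates(embryo, frame)
    frames4 <- Reduce(intersect, lapply(four, function(cl)
      co$frame[co$cell == cl]))
    if (length(frames4)) {
      f4 <- min(frames4)
      pos4 <- t(vapply(four, function(cl) {
        r <- co[co$cell == cl & co$frame == f4, ]
        c(r$ap, r$dv, r$lr)
      }, numeric(3)))
      axis_ab <- pos4["ABp", ] - pos4["ABa", ]
      ang <- angle_deg(axis_ab, c(1, 0, 0))
      ang <- min(ang, 180 - ang)
      dmat <- as.matrix(stats::dist(pos4))
      mean_adj <- mean(dmat[upper.tri(dmat)])
      t_arr <- ang < 30 && dmat["P2", "ABp"] > 1.5 * mean_adj
    }
  }

  structure(list(ems_skew = ems_skew, msap_inversion = msap_inversion,
                 extra_P4_divisions = extra_p4,
                 ab_p1_asynchrony_min = asyn, t_arrangement = t_arr),
            class = "phenotype_flags")
}

#' Assemble the embryos-by-(cell, feature) table for a stage
#'
#' Extracts features for every embryo and reshapes them into one row per
#' embryo with columns named `<cell>.<feature>` (e.g. `Ca.netdis`),
#' restricted to the cumulative cell cohort of the requested stage, plus
#' `embryo_id`, `group` and `outcome` columns.
#'
#' @param embryos named list of `embryo_lineage`.
#' @param reference a `reference_model`.
#' @param stage one of 4, 8, 15, 28 or `"all"`.
#' @param alignments optional named list of `temporal_alignment` (computed
#'   against the reference curve when omitted).
#' @return data.frame, one row per embryo; missing feature values are
#'   `NA`.
#' @export
feature_table <- function(embryos, reference, stage = 15,
                          alignments = NULL) {
  cells <- .stage_cells(stage)
  rows <- lapply(names(embryos), function(id) {
    e <- embryos[[id]]
    al <- if (!is.null(alignments)) alignments[[id]]
          else tryCatch(temporal_align(e, reference$curve),
                        error = function(err) NULL)
    fe <- tryCatch(
      suppressWarnings(extract_features(e, alignment = al,
                                        reference = reference)),
      error = function(err) NULL)
    vals <- stats::setNames(
      rep(NA_real_, length(cells) * length(.feature_names)),
      as.vector(t(outer(cells, .feature_names, paste, sep = "."))))
    if (!is.null(fe)) {
      for (cl in intersect(cells, fe$cell)) {
        r <- fe[fe$cell == cl, ]
        vals[paste(cl, .feature_names, sep = ".")] <-
          unlist(r[.feature_names])
      }
    }
    cbind(data.frame(embryo_id = id, group = e$metadata$group,
                     outcome = e$metadata$outcome,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
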