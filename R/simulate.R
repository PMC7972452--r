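# Synthetic embryo-lineage generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# canonical Sulston topology to ~100 cells, lineage-specific division
# clocks, 3D nuclear positions packed inside an ellipsoidal eggshell by
# soft-sphere relaxation, AB-P1 division asynchrony that shrinks with
# relative AB size, and planted dead-embryo signatures (dorsal shift of
# ABar progeny, Ca motility inflation, MS division-angle skew, EMS skew,
# extra germline divisions). It is not a mechanical model of the embryo;
# it only needs to be self-consistent, since the reference model is built
# from simulated controls.

#' Default per-lineage division clock table
#'
#' Mean cell-cycle durations in minutes per founder lineage and
#' within-lineage generation, loosely patterned on early C. elegans
#' development at 17 C: AB descendants cycle fast and nearly
#' synchronously, P1-derived lineages (MS, E, C, D, germline) cycle
#' progressively slower. The germline precursor P4 divides once into
#' Z2/Z3, which are quiescent.
#'
#' @return data.frame with columns `founder`, `generation`, `mean_min`.
#' @export
default_clock_table <- function() {
  rbind(
    data.frame(founder = "AB", generation = 0:6,
               mean_min = c(17, 15, 15, 15, 16, 18, 22)),
    data.frame(founder = "MS", generation = 0:3,
               mean_min = c(21, 24, 26, 28)),
    data.frame(founder = "E", generation = 0:2,
               mean_min = c(24, 35, 40)),
    data.frame(founder = "C", generation = 0:3,
               mean_min = c(19, 22, 25, 28)),
    data.frame(founder = "D", generation = 0:2,
               mean_min = c(28, 30, 32)),
    # early P-lineage intermediates keyed by their own name
    data.frame(founder = c("EMS", "P2", "P3", "P4"), generation = 0L,
               mean_min = c(14, 16, 22, 40)),
    # Z2/Z3 cycle used only when an extra germline division is planted
    data.frame(founder = "P4", generation = 1L, mean_min = 35))
}

#' Planted group-effect configuration
#'
#' Magnitudes of the perturbations the simulator plants. The cell-cycle
#' coupling to AB size reproduces the direction and rough size of the
#' reported phenotypes (P1-lineage acceleration upon equalization, with
#' the germline precursor P4 most affected); the dead-embryo signature
#' magnitudes are calibration knobs of the simulator, not measured values.
#'
#' @param p1_clock_scaling fractional P1-lineage cell-cycle shortening per
#'   percentage point of AB size below 60\%.
#' @param p4_clock_scaling same, for the P4 cell specifically (~33\%
#'   shortening at equalized sizes).
#' @param abar_dv_shift_um dorsal shift (micrometres) applied to ABar
#'   progeny in dying embryos.
#' @param ca_netdis_inflation multiplier on Ca's frame-to-frame motility
#'   in dying embryos.
#' @param ms_angle_skew_sd_deg SD (degrees) of the planted MS
#'   division-axis skew in dying embryos.
#' @param extra_p4_division_prob probability that a dying embryo's
#'   germline lineage divides at least once beyond Z2/Z3.
#' @param ems_skew_prob probability of a planted >35 degree EMS division
#'   skew in dying embryos.
#' @param compression_coupling fractional dorsoventral flattening per
#'   micrometre of mounting below the nominal eggshell height.
#' @return named list of class `perturbation_config`.
#' @export
perturbation_config <- function(p1_clock_scaling = 0.02,
                                p4_clock_scaling = 0.035,
                                abar_dv_shift_um = 2.5,
                                ca_netdis_inflation = 2.5,
                                ms_angle_skew_sd_deg = 30,
                                extra_p4_division_prob = 0.35,
                                ems_skew_prob = 0.19,
                                compression_coupling = 0.01) {
  stopifnot(extra_p4_division_prob >= 0, extra_p4_division_prob <= 1,
            ems_skew_prob >= 0, ems_skew_prob <= 1,
            is.finite(abar_dv_shift_um))
  structure(as.list(environment()), class = "perturbation_config")
}

#' Simulation configuration
#'
#' Defaults encode the study conditions: group sizes 10/18/21/28/7
#' (wild type / control / equalized alive / equalized dead / inverted),
#' relative AB size ~60\% in unmanipulated embryos, 48-53\% in equalized
#' ones and <48\% in inverted ones, a 2.5-minute frame interval, an
#' approximately 50 x 30 x 25 micrometre eggshell, and a fraction of
#' recordings truncated at the 26-cell stage.
#'
#' @param seed root RNG seed.
#' @param n_embryos named integer vector of embryos per group.
#' @param ab_size_mean,ab_size_sd named numeric vectors (percent) per
#'   group; equalized draws are clipped to \[48, 53\] and inverted ones to
#'   below 48, matching the group definitions.
#' @param eggshell_half_axes half-axes (micrometres) of the eggshell
#'   ellipsoid along A-P, D-V, L-R.
#' @param frame_interval_min recording interval (minutes).
#' @param clock_table see [default_clock_table()].
#' @param positional_sd_um per-frame Gaussian positional noise SD.
#' @param timing_cv lognormal coefficient of variation of cell-cycle
#'   durations.
#' @param pose_jitter_deg SD of the random imaging-pose rotation (part of
#'   the noise model; zero gives embryos recorded in the canonical frame).
#' @param compression_mean_um,compression_sd_um distribution of the
#'   mounted sample height (micrometres).
#' @param asynchrony_intercept_min,asynchrony_slope_min_per_pct AB-P1
#'   division asynchrony model: `intercept + slope * (AB\% - 50)` minutes,
#'   i.e. ~3.5 min at 60\% AB with a residual ~0.5 min at equal sizes.
#' @param perturbations a [perturbation_config()].
#' @param truncation_fraction fraction of embryos recorded only to the
#'   26-cell stage.
#' @param max_cells stop the recording once this many cells are alive.
#' @param t_max_min hard stop of the recording clock.
#' @param relax_iterations soft-sphere relaxation sweeps per frame.
#' @param packing_fraction fraction of eggshell volume occupied by cells
#'   (sets cell radii via the per-cell volume fraction).
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_embryos = c(wild_type = 10, control = 18,
                                     equalized_alive = 21,
                                     equalized_dead = 28, inverted = 7),
                       ab_size_mean = c(wild_type = 60, control = 60,
                                        equalized_alive = 50.6,
                                        equalized_dead = 50.6,
                                        inverted = 45.5),
                       ab_size_sd = c(wild_type = 1.2, control = 1.2,
                                      equalized_alive = 1.2,
                                      equalized_dead = 1.2,
                                      inverted = 1.5),
                       eggshell_half_axes = c(25, 15, 12.5),
                       frame_interval_min = 2.5,
                       clock_table = default_clock_table(),
                       positional_sd_um = 0.35,
                       timing_cv = 0.06,
                       pose_jitter_deg = 8,
                       compression_mean_um = 22,
                       compression_sd_um = 1.5,
                       asynchrony_intercept_min = 0.5,
                       asynchrony_slope_min_per_pct = 0.3,
                       perturbations = perturbation_config(),
                       truncation_fraction = 0.15,
                       max_cells = 100L,
                       t_max_min = 130,
                       relax_iterations = 10L,
                       packing_fraction = 0.6) {
  stopifnot(positional_sd_um >= 0, timing_cv >= 0, pose_jitter_deg >= 0,
            all(ab_size_sd >= 0),
            all(ab_size_mean > 30), all(ab_size_mean < 70),
            truncation_fraction >= 0, truncation_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# mean cycle duration lookup; falls back to the deepest tabulated
# generation of the founder lineage
.cycle_mean <- function(clock, cell) {
  if (cell %in% c("EMS", "P2", "P3", "P4")) {
    row <- clock[clock$founder == cell & clock$generation == 0L, ]
    return(row$mean_min[1])
  }
  fo <- founder_of(cell)
  founder <- fo$founder
  gen <- .lineage_generation(cell)
  hit <- clock[clock$founder == founder & clock$generation == gen, ]
  if (nrow(hit)) return(hit$mean_min[1])
  sub <- clock[clock$founder == founder, ]
  sub$mean_min[which.max(sub$generation)]
}

# canonical division axis for a mother cell, in the canonical frame
# (x = A-P with anterior negative, y = D-V with ventral positive,
# z = L-R). a/p daughters separate along -x (first daughter anterior),
# l/r along -z, and the named P-lineage divisions have fixed oblique
# axes so that MS-lineage cells end up ventral and C dorsal. A small
# deterministic per-cell tilt avoids exactly collinear geometry.
.division_axis <- function(cell) {
  base <- switch(cell,
    P0  = c(-1, 0, 0),
    P1  = c(-0.9, 0.44, 0),          # EMS anterior-ventral of P2
    EMS = c(-0.7, 0.71, 0.08),       # MS anterior-ventral of E
    P2  = c(-0.2, -0.9, 0.38),       # C dorsal of P3
    P3  = c(-0.9, 0.3, 0.3),
    P4  = c(-1, 0.2, 0),
    MS  = c(-0.72, 0.2, 0.66),       # MSa leftward: gives MSa/MSp distinct
    NULL)                            # L-R coordinates (inversion scoring)
  if (is.null(base)) {
    d1 <- sulston_daughters(cell)[1]
    suffix <- substring(d1, nchar(d1), nchar(d1))
    base <- switch(suffix, a = c(-1, 0, 0), l = c(0, 0, -1),
                   d = c(0, -1, 0), c(-1, 0, 0))
    # deterministic tilt from the cell name, identical across embryos
    h <- sum(utf8ToInt(cell) * seq_along(utf8ToInt(cell)))
    ang <- ((h %% 41) - 20) / 20 * 0.35     # up to ~20 degrees
    perp <- switch(suffix, l = c(1, 0, 0), c(0, (h %% 2) * 2 - 1, 0.3))
    base <- base + ang * perp
  }
  unit_vector(base)
}

# rotate vector v by `deg` degrees about unit axis k (Rodrigues)
.rotate_about <- function(v, k, deg) {
  th <- deg * pi / 180
  k <- unit_vector(k)
  v * cos(th) + pracma_cross(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# one soft-sphere relaxation pass: resolve pairwise overlaps, then keep
# nuclei inside the (possibly compressed) eggshell ellipsoid
.relax_positions <- function(pos, radii, half_axes, iters) {
  n <- nrow(pos)
  for (it in seq_len(iters)) {
    if (n >= 2L) {
      dx <- outer(pos[, 1], pos[, 1], "-")
      dy <- outer(pos[, 2], pos[, 2], "-")
      dz <- outer(pos[, 3], pos[, 3], "-")
      d <- sqrt(dx^2 + dy^2 + dz^2)
      target <- 0.85 * outer(radii, radii, "+")
      ov <- which(d < target & upper.tri(d), arr.ind = TRUE)
      if (nrow(ov)) {
        for (r in seq_len(nrow(ov))) {
          i <- ov[r, 1]; j <- ov[r, 2]
          delta <- pos[i, ] - pos[j, ]
          dd <- sqrt(sum(delta^2))
          dir <- if (dd < 1e-9) c(1, 0, 0) else delta / dd
          push <- 0.5 * (target[i, j] - dd)
          pos[i, ] <- pos[i, ] + dir * push
          pos[j, ] <- pos[j, ] - dir * push
        }
      }
    }
    # project centres back inside the shell, leaving room for the nucleus
    hx <- pmax(half_axes[1] * 0.98 - 0.5 * radii, 1)
    hy <- pmax(half_axes[2] * 0.98 - 0.5 * radii, 1)
    hz <- pmax(half_axes[3] * 0.98 - 0.5 * radii, 1)
    s <- sqrt((pos[, 1] / hx)^2 + (pos[, 2] / hy)^2 + (pos[, 3] / hz)^2)
    out <- s > 1
    if (any(out)) pos[out, ] <- pos[out, , drop = FALSE] / s[out]
  }
  pos
}

# division schedule: one row per cell with birth/division times, volume
# fraction and mother. Times in minutes from the 2-cell stage.
.division_schedule <- function(config, ab_size, planted, seed) {
  clock <- config$clock_table
  cv <- config$timing_cv
  p <- config$perturbations
  p1_scale <- max(0.55, 1 - p$p1_clock_scaling * (60 - ab_size))
  p4_scale <- max(0.5, 1 - p$p4_clock_scaling * (60 - ab_size))

  with_seed(derive_seed(seed, "schedule"), {
    noise <- function() stats::rlnorm(1, meanlog = -cv^2 / 2, sdlog = cv)
    ab_cycle <- .cycle_mean(clock, "AB") * noise()
    asyn <- max(0.1, (config$asynchrony_intercept_min +
                      config$asynchrony_slope_min_per_pct * (ab_size - 50))) *
      noise()
    rows <- list(
      data.frame(cell = "AB", parent = NA_character_, birth = 0,
                 division = ab_cycle, volfrac = ab_size / 100,
                 stringsAsFactors = FALSE),
      data.frame(cell = "P1", parent = NA_character_, birth = 0,
                 division = ab_cycle + asyn, volfrac = 1 - ab_size / 100,
                 stringsAsFactors = FALSE))
    frontier <- c(1L, 2L)
    while (length(frontier)) {
      nxt <- integer(0)
      for (i in frontier) {
        row <- rows[[i]]
        if (!is.finite(row$division) || row$division > config$t_max_min)
          next
        daughters <- sulston_daughters(row$cell)
        for (dn in daughters) {
          # germline cells are quiescent unless an extra division is
          # planted, in which case Z2 repeats a D-like fast division
          divides <- !startsWith(dn, "Z") ||
            (dn == "Z2" && isTRUE(planted$extra_p4))
          fo <- founder_of(dn)$super_lineage
          scale <- if (fo == "P1") {
            if (dn == "P4") p4_scale else p1_scale
          } else 1
          if (isTRUE(planted$extra_p4) && dn %in% c("P4", "Z2"))
            scale <- scale * 0.7
          cyc <- .cycle_mean(clock, dn) * scale * noise()
          div_t <- if (divides) row$division + cyc else Inf
          rows[[length(rows) + 1L]] <- data.frame(
            cell = dn, parent = row$cell, birth = row$division,
            division = div_t, volfrac = row$volfrac / 2,
            stringsAsFactors = FALSE)
          nxt <- c(nxt, length(rows))
        }
      }
      frontier <- nxt
    }
    do.call(rbind, rows)
  })
}

#' Simulate one embryo lineage
#'
#' Generates a tracked lineage from the 2-cell stage until ~`max_cells`
#' cells (26 cells for truncated recordings). Divisions fire at
#' clock-sampled times; daughters are placed astride the mother along the
#' cell's canonical division axis; after every frame, positions relax by
#' pairwise soft-sphere repulsion and are projected back inside the
#' eggshell ellipsoid. Group-specific effects (AB-size-coupled P1-lineage
#' acceleration, dead-embryo signatures) are applied per the
#' configuration. Deterministic given `(config, group, seed)`.
#'
#' @param config a [sim_config()].
#' @param group group label (must have entries in the config's group
#'   vectors).
#' @param seed integer seed for this embryo.
#' @param embryo_id identifier (default derived from group and seed).
#' @param truncated force recording truncation at the 26-cell stage
#'   (default: drawn from `config$truncation_fraction`).
#' @return an `embryo_lineage` with populated metadata; the planted
#'   signature draw is attached as attribute `planted`.
#' @export
simulate_embryo <- function(config, group, seed,
                            embryo_id = sprintf("%s_%04d", group, seed),
                            truncated = NULL) {
  if (!group %in% names(config$n_embryos))
    stop("group '", group, "' unknown to the simulation config",
         call. = FALSE)
  if (any(config$eggshell_half_axes < 5))
    stop("geometry error: eggshell too small to contain the lineage",
         call. = FALSE)
  p <- config$perturbations
  dead_group <- group %in% c("equalized_dead", "inverted")

  draws <- with_seed(derive_seed(seed, "embryo-draws"), {
    m <- config$ab_size_mean[[group]]
    s <- config$ab_size_sd[[group]]
    ab <- stats::rnorm(1, m, s)
    ab <- switch(group,
                 equalized_alive = min(53, max(48, ab)),
                 equalized_dead = min(53, max(48, ab)),
                 inverted = min(47.9, ab),
                 ab)
    list(
      ab_size = ab,
      compression = stats::rnorm(1, config$compression_mean_um,
                                 config$compression_sd_um),
      truncated = stats::runif(1) < config$truncation_fraction,
      extra_p4 = dead_group && stats::runif(1) < p$extra_p4_division_prob,
      ems_skew = dead_group && stats::runif(1) < p$ems_skew_prob,
      ms_skew_deg = if (dead_group)
        stats::rnorm(1, 0, p$ms_angle_skew_sd_deg) else 0,
      abar_shift = dead_group,
      pose = with_seed(derive_seed(seed, "pose"), {
        if (config$pose_jitter_deg > 0) {
          ang <- stats::rnorm(3, 0, config$pose_jitter_deg)
          Rx <- rotmat(1, ang[1]); Ry <- rotmat(2, ang[2])
          Rz <- rotmat(3, ang[3])
          Rz %*% Ry %*% Rx
        } else diag(3)
      }))
  })
  if (!is.null(truncated)) draws$truncated <- truncated

  sched <- .division_schedule(config, draws$ab_size, draws, seed)
  dt <- config$frame_interval_min

  # recording end: when the live-cell count reaches the cap
  cap <- if (draws$truncated) 26L else config$max_cells
  ev_t <- sort(sched$division[is.finite(sched$division)])
  count_at <- function(t) sum(sched$birth <= t & sched$division > t)
  t_end <- config$t_max_min
  for (te in ev_t) {
    if (count_at(te + 1e-6) >= cap) { t_end <- te + dt; break }
  }
  t_end <- min(t_end, config$t_max_min)
  frames <- seq(0, t_end, by = dt)

  # eggshell possibly flattened dorsoventrally by mounting compression
  he <- config$eggshell_half_axes
  nominal_height <- 2 * he[3]
  squeeze <- 1 - p$compression_coupling *
    max(0, nominal_height - draws$compression)
  he_eff <- c(he[1], he[2] * squeeze, he[3] * squeeze)

  v_eff <- config$packing_fraction * 4 / 3 * pi * prod(he)
  radius_of <- function(volfrac) (3 * volfrac * v_eff / (4 * pi))^(1 / 3)

  # planted geometry modifiers
  abar_bias <- if (draws$abar_shift) c(0, -p$abar_dv_shift_um, 0) else c(0, 0, 0)

  axis_of <- function(cell) {
    ax <- .division_axis(cell)
    if (cell == "EMS" && draws$ems_skew)
      ax <- .rotate_about(ax, c(0, 0, 1), 50)
    if (cell == "MS" && draws$ms_skew_deg != 0)
      ax <- .rotate_about(ax, c(0, 1, 0), draws$ms_skew_deg)
    ax
  }

  obs <- with_seed(derive_seed(seed, "geometry"), {
    pos <- rbind(AB = c(-he[1] * 0.4, 0, 0), P1 = c(he[1] * 0.45, 0, 0))
    out <- vector("list", length(frames))
    for (k in seq_along(frames)) {
      t <- frames[k]
      alive <- sched$cell[sched$birth <= t &
                            (sched$division > t | !is.finite(sched$division))]
      born <- setdiff(alive, rownames(pos))
      for (cell in born) {
        row <- sched[sched$cell == cell, ]
        mother <- row$parent
        mpos <- if (mother %in% rownames(pos)) pos[mother, ]
                else c(0, 0, 0)
        d1 <- sulston_daughters(mother)[1]
        ax <- axis_of(mother)
        sgn <- if (cell == d1) 1 else -1
        sep <- 0.8 * radius_of(row$volfrac)
        pos <- rbind(pos, matrix(mpos + sgn * sep * ax, 1, 3,
                                 dimnames = list(cell, NULL)))
      }
      pos <- pos[rownames(pos) %in% alive, , drop = FALSE]
      radii <- radius_of(sched$volfrac[match(rownames(pos), sched$cell)])
      pos <- .relax_positions(pos, radii, he_eff, config$relax_iterations)
      if (config$positional_sd_um > 0) {
        sd_cell <- rep(config$positional_sd_um, nrow(pos))
        # inflated motility of Ca in dying embryos
        if (draws$abar_shift)
          sd_cell[rownames(pos) == "Ca"] <-
            sd_cell[rownames(pos) == "Ca"] * p$ca_netdis_inflation
        pos <- pos + matrix(stats::rnorm(length(pos), 0, sd_cell),
                            nrow(pos), 3)
      }
      # planted dorsal displacement of ABar progeny (post-relaxation bias)
      is_abar <- startsWith(rownames(pos), "ABar")
      rec <- pos
      if (any(is_abar))
        rec[is_abar, ] <- rec[is_abar, , drop = FALSE] +
          matrix(abar_bias, sum(is_abar), 3, byrow = TRUE)
      out[[k]] <- data.frame(cell = rownames(rec), frame = k,
                             time_min = t, x = rec[, 1], y = rec[, 2],
                             z = rec[, 3],
                             diameter = 2 * radii,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })

  # imaging pose: rotate the canonical frame into an arbitrary recording
  # orientation and decentre slightly
  xyz <- as.matrix(obs[, c("x", "y", "z")]) %*% t(draws$pose)
  obs$x <- xyz[, 1]; obs$y <- xyz[, 2]; obs$z <- xyz[, 3]

  obs$parent <- sched$parent[match(obs$cell, sched$cell)]
  d <- obs[, c("cell", "frame", "time_min", "x", "y", "z", "diameter",
               "parent")]

  md <- embryo_metadata(
    group = group, relative_AB_size = draws$ab_size,
    compression_um = draws$compression,
    frame_interval_min = dt,
    outcome = if (group %in% c("wild_type", "control", "equalized_alive"))
      "alive" else if (dead_group) "dead" else "unknown")
  emb <- embryo_lineage(embryo_id, d, md)
  attr(emb, "planted") <- draws[c("ab_size", "extra_p4", "ems_skew",
                                  "ms_skew_deg", "abar_shift", "truncated")]
  emb
}

rotmat <- function(axis, deg) {
  th <- deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  switch(axis,
         matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, 3, byrow = TRUE),
         matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, 3, byrow = TRUE),
         matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE))
}

#' Simulate a full cohort of embryos
#'
#' Draws `config$n_embryos` embryos per group, assigns outcome labels
#' consistently with the planted signatures, and optionally writes
#' native-format lineage files, the metadata CSV and the planted-truth
#' JSON to a directory.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list with `embryos` (named list of `embryo_lineage`),
#'   `metadata` (data.frame) and `truth` (see [planted_truth()]).
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  embryos <- list()
  meta <- list()
  idx <- 0L
  for (group in names(config$n_embryos)) {
    n <- config$n_embryos[[group]]
    for (i in seq_len(n)) {
      idx <- idx + 1L
      eseed <- derive_seed(config$seed, paste0("cohort-", group), i)
      id <- sprintf("%s_%02d", group, i)
      emb <- simulate_embryo(config, group, eseed, embryo_id = id)
      embryos[[id]] <- emb
      meta[[id]] <- data.frame(
        embryo_id = id, group = group,
        relative_AB_size = emb$metadata$relative_AB_size,
        compression_um = emb$metadata$compression_um,
        outcome = emb$metadata$outcome,
        frame_interval_min = emb$metadata$frame_interval_min,
        truncated = attr(emb, "planted")$truncated,
        stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  truth <- planted_truth(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_native(embryos, file.path(out_dir, "lineages.tsv"))
    write_metadata(metadata, file.path(out_dir, "metadata.csv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(embryos = embryos, metadata = metadata, truth = truth)
}

#' Planted ground-truth table
#'
#' Reports, per (cell pattern, feature), which group differences the
#' configuration plants between dying and surviving equalized embryos and
#' their nominal magnitudes -- the truth against which the screening and
#' classification stages can be scored.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `cell_pattern`, `feature`,
#'   `effect_type`, `magnitude`.
#' @export
planted_truth <- function(config) {
  p <- config$perturbations
  rows <- list()
  add <- function(pattern, feature, type, mag) {
    rows[[length(rows) + 1L]] <<- data.frame(
      cell_pattern = pattern, feature = feature, effect_type = type,
      magnitude = mag, stringsAsFactors = FALSE)
  }
  if (p$abar_dv_shift_um != 0)
    add("^ABar", "pDV", "shift_um", -p$abar_dv_shift_um)
  if (p$ca_netdis_inflation != 1) {
    add("^Ca$", "netdis", "inflation", p$ca_netdis_inflation)
    add("^Ca$", "totdis", "inflation", p$ca_netdis_inflation)
  }
  if (p$ms_angle_skew_sd_deg != 0)
    add("^MS$", "aMean", "skew_sd_deg", p$ms_angle_skew_sd_deg)
  if (p$extra_p4_division_prob > 0)
    add("^(P4|Z2|Z3)", "extra_division", "probability",
        p$extra_p4_division_prob)
  if (p$ems_skew_prob > 0)
    add("^EMS$", "aMean", "skew_probability", p$ems_skew_prob)
  if (!length(rows))
    return(data.frame(cell_pattern = character(), feature = character(),
                      effect_type = character(), magnitude = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
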