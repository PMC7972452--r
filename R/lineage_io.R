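# Reading, validating and writing tracked-lineage data.
#
# The native interchange format is a plain delimited table (TSV by default,
# comma accepted) with one row per nucleus observation:
#   embryo_id, cell_name, frame, time_min, x, y, z, diameter, parent_name
# Coordinates are continuous micrometres in the right-handed imaging frame;
# frames are 1-based.

.native_columns <- c("embryo_id", "cell_name", "frame", "time_min",
                     "x", "y", "z", "diameter", "parent_name")

#' Construct an embryo lineage object
#'
#' An `embryo_lineage` bundles one embryo's tracked nuclei (long-format
#' data.frame, one row per cell per frame) with its metadata. Tracks are
#' validated on construction: frames strictly increasing within a cell,
#' each cell has 0 or exactly 2 daughters, daughters appear only after the
#' mother's last frame, and parents resolve to tracked cells (root cells
#' carry `NA` parents).
#'
#' @param embryo_id identifier string.
#' @param data data.frame with columns `cell`, `frame`, `time_min`, `x`,
#'   `y`, `z`, `diameter`, `parent`.
#' @param metadata named list; see [embryo_metadata()].
#' @param validate set `FALSE` to skip structural checks (internal use).
#' @return an object of class `embryo_lineage`.
#' @export
embryo_lineage <- function(embryo_id, data, metadata = embryo_metadata(),
                           validate = TRUE) {
  need <- c("cell", "frame", "time_min", "x", "y", "z", "diameter", "parent")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  data$cell <- as.character(data$cell)
  data$parent <- as.character(data$parent)
  data <- data[order(data$cell, data$frame), need, drop = FALSE]
  rownames(data) <- NULL
  obj <- structure(list(embryo_id = as.character(embryo_id),
                        data = data, metadata = metadata),
                   class = "embryo_lineage")
  if (validate) validate_lineage(obj)
  obj
}

#' Embryo metadata record
#'
#' @param group one of `wild_type`, `control`, `equalized_alive`,
#'   `equalized_dead`, `inverted`, `synthetic`.
#' @param relative_AB_size AB size as percent of the embryo cross-section,
#'   in (0, 100).
#' @param compression_um mounted sample height in micrometres (optional).
#' @param frame_interval_min recording interval in minutes.
#' @param outcome `alive`, `dead` or `unknown`.
#' @return named list of class `embryo_metadata`.
#' @export
embryo_metadata <- function(group = "synthetic", relative_AB_size = NA_real_,
                            compression_um = NA_real_,
                            frame_interval_min = 2.5, outcome = "unknown") {
  groups <- c("wild_type", "control", "equalized_alive", "equalized_dead",
              "inverted", "synthetic")
  if (!group %in% groups)
    stop("unknown group '", group, "'", call. = FALSE)
  if (!outcome %in% c("alive", "dead", "unknown"))
    stop("unknown outcome '", outcome, "'", call. = FALSE)
  if (!is.na(relative_AB_size) &&
      (relative_AB_size <= 0 || relative_AB_size >= 100))
    stop("relative_AB_size must be in (0, 100)", call. = FALSE)
  structure(list(group = group, relative_AB_size = relative_AB_size,
                 compression_um = compression_um,
                 frame_interval_min = frame_interval_min, outcome = outcome),
            class = "embryo_metadata")
}

#' @export
print.embryo_lineage <- function(x, ...) {
  cat("<embryo_lineage> ", x$embryo_id, "\n", sep = "")
  cat("  cells: ", length(unique(x$data$cell)),
      ", observations: ", nrow(x$data), "\n", sep = "")
  cat("  group: ", x$metadata$group, ", outcome: ", x$metadata$outcome,
      "\n", sep = "")
  invisible(x)
}

#' Validate the track structure of an embryo lineage
#'
#' @param embryo an `embryo_lineage`.
#' @return the object, invisibly; stops with an informative error when a
#'   structural invariant is violated.
#' @export
validate_lineage <- function(embryo) {
  d <- embryo$data
  key <- paste(d$cell, d$frame)
  if (anyDuplicated(key))
    stop("duplication error: duplicate (cell, frame) in embryo '",
         embryo$embryo_id, "': ", key[duplicated(key)][1], call. = FALSE)
  by_cell <- split(seq_len(nrow(d)), d$cell)
  first_frame <- vapply(by_cell, function(i) min(d$frame[i]), numeric(1))
  last_frame  <- vapply(by_cell, function(i) max(d$frame[i]), numeric(1))
  parent_of <- vapply(by_cell, function(i) d$parent[i][1], character(1))
  for (cell in names(by_cell)) {
    fr <- d$frame[by_cell[[cell]]]
    if (any(diff(fr) <= 0))
      stop("structure error: frames not strictly increasing for cell '",
           cell, "'", call. = FALSE)
  }
  known <- names(by_cell)
  ext_parent <- parent_of[!is.na(parent_of) & !(parent_of %in% known)]
  if (length(ext_parent))
    stop("structure error: parent '", ext_parent[1],
         "' of a tracked cell is not tracked and not marked as root",
         call. = FALSE)
  kids <- split(names(by_cell)[!is.na(parent_of)],
                parent_of[!is.na(parent_of)])
  kids <- kids[names(kids) %in% known]  # root parents checked above
  for (p in names(kids)) {
    if (length(kids[[p]]) != 2L)
      stop("structure error: cell '", p, "' has ", length(kids[[p]]),
           " daughter(s); expected 0 or 2", call. = FALSE)
    if (any(first_frame[kids[[p]]] <= last_frame[p]))
      stop("structure error: daughters of '", p,
           "' overlap their mother's track in time", call. = FALSE)
  }
  invisible(embryo)
}

#' Per-cell track summaries
#'
#' @param embryo an `embryo_lineage`.
#' @return data.frame with one row per cell: `cell`, `parent`,
#'   `n_daughters`, `first_frame`, `last_frame`, `first_time`, `last_time`.
#' @export
cell_tracks <- function(embryo) {
  d <- embryo$data
  by_cell <- split(seq_len(nrow(d)), d$cell)
  cells <- names(by_cell)
  parent <- vapply(by_cell, function(i) d$parent[i][1], character(1))
  n_d <- vapply(cells, function(cl) sum(parent == cl, na.rm = TRUE),
                numeric(1))
  data.frame(
    cell = cells, parent = unname(parent), n_daughters = unname(n_d),
    first_frame = vapply(by_cell, function(i) min(d$frame[i]), numeric(1)),
    last_frame  = vapply(by_cell, function(i) max(d$frame[i]), numeric(1)),
    first_time  = vapply(by_cell, function(i) min(d$time_min[i]), numeric(1)),
    last_time   = vapply(by_cell, function(i) max(d$time_min[i]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Read lineages from the native long-format table
#'
#' @param path delimited text file (TSV default; comma autodetected) with
#'   columns `embryo_id`, `cell_name`, `frame`, `time_min`, `x`, `y`, `z`,
#'   `diameter`, `parent_name`.
#' @param metadata optional metadata table (as from [read_metadata()]) used
#'   to attach group/outcome information per embryo.
#' @return named list of `embryo_lineage`, one per `embryo_id`.
#' @export
read_native <- function(path, metadata = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  miss <- setdiff(.native_columns, names(tab))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(tab, tab$embryo_id), function(sub) {
    d <- data.frame(cell = sub$cell_name, frame = as.integer(sub$frame),
                    time_min = as.numeric(sub$time_min),
                    x = as.numeric(sub$x), y = as.numeric(sub$y),
                    z = as.numeric(sub$z),
                    diameter = as.numeric(sub$diameter),
                    parent = as.character(sub$parent_name),
                    stringsAsFactors = FALSE)
    md <- embryo_metadata()
    if (!is.null(metadata)) {
      row <- metadata[metadata$embryo_id == sub$embryo_id[1], , drop = FALSE]
      if (nrow(row) == 1L)
        md <- embryo_metadata(group = row$group,
                              relative_AB_size = row$relative_AB_size,
                              compression_um = row$compression_um,
                              frame_interval_min = row$frame_interval_min,
                              outcome = row$outcome)
    }
    embryo_lineage(sub$embryo_id[1], d, md)
  })
  out[order(names(out))]
}

#' Write lineages to the native long-format table
#'
#' Inverse of [read_native()]: `read_native(write_native(x, f))` restores
#' the same lineages up to floating-point formatting.
#'
#' @param embryos an `embryo_lineage` or list of them.
#' @param path output file.
#' @param sep field separator (tab default).
#' @return `path`, invisibly.
#' @export
write_native <- function(embryos, path, sep = "\t") {
  if (inherits(embryos, "embryo_lineage")) embryos <- list(embryos)
  rows <- lapply(embryos, function(e) {
    data.frame(embryo_id = e$embryo_id, cell_name = e$data$cell,
               frame = e$data$frame, time_min = e$data$time_min,
               x = e$data$x, y = e$data$y, z = e$data$z,
               diameter = e$data$diameter, parent_name = e$data$parent,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the per-embryo metadata table
#'
#' CSV with columns `embryo_id`, `group`, `relative_AB_size`,
#' `compression_um`, `outcome`, `frame_interval_min`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("embryo_id", "group", "relative_AB_size", "compression_um",
            "outcome", "frame_interval_min")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("format error: metadata missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tab
}

#' @rdname read_metadata
#' @param metadata data.frame as returned by [read_metadata()].
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a StarryNite/AceTree nuclei export
#'
#' Best-effort reader for the per-timepoint comma-separated
#' \code{t###-nuclei} files written by StarryNite and edited in AceTree:
#' one file per frame, one row per detected nucleus, with a predecessor
#' index into the previous frame and up to two successor indices into the
#' next. Tracks are reconstructed by following those indices; a nucleus
#' whose predecessor carries two successors starts a daughter track.
#' Pixel/plane coordinates are converted to micrometres with the supplied
#' calibration.
#'
#' @param path directory or zip archive containing the nuclei files.
#' @param xy_res,z_res calibration: micrometres per pixel in x/y and per
#'   plane in z. Mandatory.
#' @param frame_interval_min minutes between frames (time stamps are
#'   `(frame - 1) * frame_interval_min`).
#' @param embryo_id identifier for the returned lineage (default: the
#'   basename of `path`).
#' @param col_map named list mapping the required fields (`index`,
#'   `valid`, `pred`, `succ1`, `succ2`, `x`, `y`, `z`, `diameter`,
#'   `name`) to 1-based column positions; the default is the classic
#'   AceTree layout. Exposed because deposited exports vary.
#' @param metadata an [embryo_metadata()] record.
#' @return an `embryo_lineage`.
#' @export
read_starrynite <- function(path, xy_res, z_res, frame_interval_min = 2.5,
                            embryo_id = NULL, col_map = NULL,
                            metadata = embryo_metadata()) {
  if (missing(xy_res) || missing(z_res) || is.null(xy_res) || is.null(z_res))
    stop("configuration error: xy_res and z_res calibration are required",
         call. = FALSE)
  cm <- list(index = 1L, valid = 2L, pred = 3L, succ1 = 4L, succ2 = 5L,
             x = 6L, y = 7L, z = 8L, diameter = 9L, name = 10L)
  if (!is.null(col_map)) cm[names(col_map)] <- col_map

  cleanup <- NULL
  if (file.exists(path) && !dir.exists(path) && grepl("\\.zip$", path)) {
    exdir <- tempfile("starrynite")
    utils::unzip(path, exdir = exdir)
    path <- exdir
    cleanup <- exdir
  }
  on.exit(if (!is.null(cleanup)) unlink(cleanup, recursive = TRUE))
  files <- list.files(path, pattern = "t[0-9]+-nuclei", recursive = TRUE,
                      full.names = TRUE)
  if (!length(files))
    stop("format error: no t###-nuclei files under '", path, "'",
         call. = FALSE)
  tp <- as.integer(sub(".*t([0-9]+)-nuclei.*", "\\1", basename(files)))
  files <- files[order(tp)]
  tp <- sort(tp)

  if (is.null(embryo_id)) embryo_id <- basename(normalizePath(path))

  # per-frame raw tables
  frames <- lapply(files, function(f) {
    raw <- utils::read.table(f, sep = ",", stringsAsFactors = FALSE,
                             strip.white = TRUE, header = FALSE,
                             blank.lines.skip = TRUE)
    raw
  })

  rows <- list()           # accumulated observations
  track_name <- character()  # track id -> cell name
  track_parent <- character()
  next_auto <- 1L
  # map from nucleus index at current frame -> track id
  prev_map <- NULL
  prev_tab <- NULL
  n_valid_total <- 0L

  for (k in seq_along(frames)) {
    tab <- frames[[k]]
    cur_map <- list()
    for (r in seq_len(nrow(tab))) {
      valid <- as.integer(tab[r, cm$valid])
      if (is.na(valid) || valid == 0L) next
      n_valid_total <- n_valid_total + 1L
      idx <- as.integer(tab[r, cm$index])
      pred <- as.integer(tab[r, cm$pred])
      nm <- if (cm$name <= ncol(tab)) trimws(as.character(tab[r, cm$name]))
            else ""
      if (k == 1L || is.na(pred) || pred <= 0L) {
        tid <- length(track_name) + 1L
        track_name[tid] <- if (nzchar(nm)) nm else {
          auto <- paste0("cell", next_auto); next_auto <- next_auto + 1L; auto
        }
        track_parent[tid] <- NA_character_
      } else {
        if (is.null(prev_map) || is.null(prev_map[[as.character(pred)]]))
          stop("structure error: broken predecessor chain at timepoint ",
               tp[k], " (nucleus ", idx, " -> predecessor ", pred, ")",
               call. = FALSE)
        ptid <- prev_map[[as.character(pred)]]
        prow <- which(as.integer(prev_tab[, cm$index]) == pred)[1]
        s1 <- as.integer(prev_tab[prow, cm$succ1])
        s2 <- as.integer(prev_tab[prow, cm$succ2])
        divided <- !is.na(s1) && !is.na(s2) && s1 > 0L && s2 > 0L
        if (divided) {
          tid <- length(track_name) + 1L
          track_name[tid] <- if (nzchar(nm)) nm else {
            auto <- paste0("cell", next_auto); next_auto <- next_auto + 1L
            auto
          }
          track_parent[tid] <- track_name[ptid]
        } else {
          tid <- ptid
          # adopt a curated name once it appears on a continuing track
          if (nzchar(nm) && startsWith(track_name[tid], "cell"))
            track_name[tid] <- nm
        }
      }
      cur_map[[as.character(idx)]] <- tid
      rows[[length(rows) + 1L]] <- data.frame(
        tid = tid, frame = tp[k],
        x = as.numeric(tab[r, cm$x]) * xy_res,
        y = as.numeric(tab[r, cm$y]) * xy_res,
        z = as.numeric(tab[r, cm$z]) * z_res,
        diameter = if (cm$diameter <= ncol(tab))
          as.numeric(tab[r, cm$diameter]) * xy_res else NA_real_,
        stringsAsFactors = FALSE)
    }
    prev_map <- cur_map
    prev_tab <- tab
  }
  if (n_valid_total == 0L) {
    warning("all nuclei flagged invalid; returning an empty embryo")
    d <- data.frame(cell = character(), frame = integer(),
                    time_min = numeric(), x = numeric(), y = numeric(),
                    z = numeric(), diameter = numeric(),
                    parent = character(), stringsAsFactors = FALSE)
    return(embryo_lineage(embryo_id, d, metadata, validate = FALSE))
  }
  obs <- do.call(rbind, rows)
  d <- data.frame(cell = track_name[obs$tid], frame = obs$frame,
                  time_min = (obs$frame - 1) * frame_interval_min,
                  x = obs$x, y = obs$y, z = obs$z, diameter = obs$diameter,
                  parent = track_parent[obs$tid], stringsAsFactors = FALSE)
  metadata$frame_interval_min <- frame_interval_min
  embryo_lineage(embryo_id, d, metadata)
}
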