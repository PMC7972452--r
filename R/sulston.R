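# Sulston-nomenclature utilities.
#
# Naming follows the canonical scheme: most daughters append a direction
# letter (a/p, l/r, d/v) to the mother's name, while the early P lineage
# uses fixed special names. The P-lineage table is explicit because the
# suffix rule does not cover it.

# mother -> daughters for the named early lineage
.p_lineage_daughters <- list(
  P0  = c("AB", "P1"),
  P1  = c("EMS", "P2"),
  EMS = c("MS", "E"),
  P2  = c("C", "P3"),
  P3  = c("D", "P4"),
  P4  = c("Z2", "Z3")
)

# daughter -> mother, derived from the table above
.p_lineage_parent <- {
  tab <- .p_lineage_daughters
  out <- character(0)
  for (m in names(tab)) out[tab[[m]]] <- m
  out
}

# roots of suffix-style naming; order matters: longest prefix wins (EMS
# must be tried before E, AB before nothing).
.name_prefixes <- c("EMS", "AB", "MS", "Z2", "Z3", "P0", "P1", "P2", "P3",
                    "P4", "E", "C", "D")

.split_cell_name <- function(cell_name) {
  for (p in .name_prefixes) {
    if (startsWith(cell_name, p)) {
      suffix <- substring(cell_name, nchar(p) + 1L)
      if (grepl("^[aplrdv]*$", suffix)) {
        # bare P0..P4 take no suffix; their descendants have special names
        if (p %in% c("P0", "P1", "P2", "P3", "P4", "EMS") && nzchar(suffix))
          next
        return(list(prefix = p, suffix = suffix))
      }
    }
  }
  stop("invalid Sulston cell name: '", cell_name, "'", call. = FALSE)
}

#' Is a string a valid Sulston or P-lineage cell name?
#' @param cell_name character vector of candidate names.
#' @return logical vector.
#' @export
is_valid_cell_name <- function(cell_name) {
  vapply(cell_name, function(nm) {
    ok <- TRUE
    tryCatch(.split_cell_name(nm), error = function(e) ok <<- FALSE)
    ok
  }, logical(1), USE.NAMES = FALSE)
}

#' Founder lineage of a cell
#'
#' Resolves a Sulston name to its founder lineage (AB, MS, E, C, D, P4 --
#' the germline cells Z2/Z3 resolve to P4) and to the AB-vs-P1
#' super-lineage. Early P-lineage intermediates (P0, P1, EMS, P2, P3)
#' resolve to themselves as founder.
#'
#' @param cell_name character vector of Sulston names.
#' @return data.frame with columns `cell`, `founder`, `super_lineage`.
#' @examples
#' founder_of(c("ABala", "Ep", "Z2"))
#' @export
founder_of <- function(cell_name) {
  res <- lapply(cell_name, function(nm) {
    parts <- .split_cell_name(nm)
    founder <- switch(parts$prefix,
      AB = "AB", MS = "MS", E = "E", C = "C", D = "D",
      Z2 = "P4", Z3 = "P4", P4 = "P4",
      parts$prefix)  # P0, P1, P2, P3, EMS resolve to themselves
    super <- if (founder == "AB") "AB" else if (parts$prefix == "P0") "P0" else "P1"
    c(founder = founder, super_lineage = super)
  })
  data.frame(cell = cell_name,
             founder = vapply(res, `[[`, "", "founder"),
             super_lineage = vapply(res, `[[`, "", "super_lineage"),
             stringsAsFactors = FALSE)
}

#' Canonical daughter names of a cell
#'
#' Early P-lineage divisions come from the explicit table
#' (P0 to AB/P1, ..., P4 to Z2/Z3); all other cells append direction
#' letters: a/p except for the second AB generation which divides
#' left/right (ABa to ABal/ABar). The first-named daughter (a or l) is the
#' conventional "first" daughter used to orient division vectors.
#'
#' @param cell_name a single Sulston name.
#' @return character vector of length 2.
#' @export
sulston_daughters <- function(cell_name) {
  if (cell_name %in% names(.p_lineage_daughters))
    return(.p_lineage_daughters[[cell_name]])
  parts <- .split_cell_name(cell_name)
  letters2 <- if (parts$prefix == "AB" && nchar(parts$suffix) == 1L)
    c("l", "r") else c("a", "p")
  paste0(cell_name, letters2)
}

#' Mother of a cell under canonical naming
#' @param cell_name a single Sulston name.
#' @return mother name, or `NA` for the zygote P0.
#' @export
sulston_parent <- function(cell_name) {
  if (cell_name == "P0") return(NA_character_)
  if (cell_name %in% names(.p_lineage_parent))
    return(unname(.p_lineage_parent[cell_name]))
  parts <- .split_cell_name(cell_name)
  if (!nzchar(parts$suffix))
    stop("cell '", cell_name, "' has no canonical mother", call. = FALSE)
  substring(cell_name, 1L, nchar(cell_name) - 1L)
}

# generation index within the founder lineage: number of divisions since
# the founder cell itself was born (founder cell -> 0). For the early P
# lineage the index counts divisions since P0.
.lineage_generation <- function(cell_name) {
  parts <- .split_cell_name(cell_name)
  extra <- switch(parts$prefix,
    P0 = 0L, AB = 0L, P1 = 0L, EMS = 0L, P2 = 0L,
    MS = 0L, E = 0L, C = 0L, P3 = 0L, D = 0L, P4 = 0L,
    Z2 = 1L, Z3 = 1L)
  nchar(parts$suffix) + extra
}

#' Cells attributed to a developmental stage
#'
#' Returns the canonical cohort of cells whose features are attributed to
#' the 4-, 8-, 15- or 28-cell stage. Membership rule: a stage cohort is one
#' synchronous division round of the canonical tree -- the 4-cell cohort is
#' the cells born from the 2-cell stage, and each later cohort contains the
#' daughters of the previous cohort's dividing cells (germline P4 divides
#' into Z2/Z3 within the 28-cell round). Cohorts are pairwise disjoint and
#' their cumulative union is the classifier's feature universe per stage.
#'
#' @param stage_k one of 4, 8, 15, 28.
#' @return character vector of cell names.
#' @examples
#' generation_cohort(4)
#' @export
generation_cohort <- function(stage_k) {
  if (!(length(stage_k) == 1L && stage_k %in% c(4, 8, 15, 28)))
    stop("stage_k must be one of 4, 8, 15, 28", call. = FALSE)
  round1 <- c("ABa", "ABp", "EMS", "P2")
  round2 <- c("ABal", "ABar", "ABpl", "ABpr", "MS", "E", "C", "P3")
  round3 <- c(unlist(lapply(c("ABal", "ABar", "ABpl", "ABpr"),
                            sulston_daughters)),
              "MSa", "MSp", "Ea", "Ep", "Ca", "Cp", "D", "P4")
  round3_div <- setdiff(round3, character(0))
  round4 <- unlist(lapply(round3_div, sulston_daughters))
  switch(as.character(stage_k),
         "4" = round1, "8" = round2, "15" = round3, "28" = round4)
}

#' Canonical lineage topology
#'
#' Expands the canonical division tree from the 2-cell stage for a given
#' number of division rounds per branch, returning one row per cell with
#' its mother, founder lineage and within-lineage generation.
#'
#' @param max_generation number of division rounds below AB and P1.
#' @return data.frame with columns `cell`, `parent`, `founder`,
#'   `super_lineage`, `generation`.
#' @export
canonical_topology <- function(max_generation = 4L) {
  rows <- list(data.frame(cell = c("AB", "P1"), parent = "P0",
                          stringsAsFactors = FALSE))
  frontier <- c("AB", "P1")
  for (g in seq_len(max_generation)) {
    nxt <- character(0)
    for (cell in frontier) {
      if (cell %in% c("Z2", "Z3")) next  # germline quiescent by default
      d <- sulston_daughters(cell)
      rows[[length(rows) + 1L]] <- data.frame(cell = d, parent = cell,
                                              stringsAsFactors = FALSE)
      nxt <- c(nxt, d)
    }
    frontier <- nxt
  }
  out <- do.call(rbind, rows)
  fo <- founder_of(out$cell)
  out$founder <- fo$founder
  out$super_lineage <- fo$super_lineage
  out$generation <- vapply(out$cell, .lineage_generation, integer(1))
  rownames(out) <- NULL
  out
}
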