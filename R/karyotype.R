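#' Arm ratio of a chromosome
#'
#' The arm ratio AR = long arm / short arm. Inputs are orientation-normalized
#' first: whichever measured arm is longer is taken as the long arm, so the
#' result is always >= 1.
#'
#' @param short Short-arm length(s), um. Must be > 0.
#' @param long Long-arm length(s), um.
#' @return Numeric vector of arm ratios, all >= 1.
#' @examples
#' arm_ratio(2, 4)    # 2
#' arm_ratio(1.3, 2.21)
#' @export
arm_ratio <- function(short, long) {
  if (any(!is.finite(short)) || any(!is.finite(long)))
    stop("arm lengths must be finite")
  if (any(short <= 0) || any(long <= 0))
    stop("arm lengths must be positive")
  pmax(short, long) / pmin(short, long)
}

#' Centromeric index
#'
#' CI = 100 * short / (short + long), the short arm's share of the chromosome
#' in percent. A metacentric chromosome has CI = 50; CI decreases as the
#' centromere moves towards the telomere.
#'
#' @inheritParams arm_ratio
#' @return Numeric vector of centromeric indices in (0, 50].
#' @export
centromeric_index <- function(short, long) {
  if (any(!is.finite(short)) || any(!is.finite(long)))
    stop("arm lengths must be finite")
  if (any(short <= 0) || any(long <= 0))
    stop("arm lengths must be positive")
  s <- pmin(short, long)
  l <- pmax(short, long)
  100 * s / (s + l)
}

#' Levan centromere-position class
#'
#' Classifies chromosomes by arm ratio into the standard centromere-position
#' classes: metacentric (m, AR in [1, 1.7]), submetacentric (sm, (1.7, 3]),
#' subtelocentric (st, (3, 7]) and acro-/telocentric (t, > 7). Boundary values
#' belong to the more symmetric class. An AR exactly 1 (Levan's strict "M"
#' point) is folded into m.
#'
#' @param AR Numeric vector of arm ratios, each >= 1.
#' @return Character vector over \code{c("m", "sm", "st", "t")}.
#' @export
classify_levan <- function(AR) {
  if (any(!is.finite(AR))) stop("AR must be finite")
  if (any(AR < 1)) stop("AR < 1: arms are not orientation-normalized")
  out <- character(length(AR))
  out[AR <= 1.7] <- "m"
  out[AR > 1.7 & AR <= 3] <- "sm"
  out[AR > 3 & AR <= 7] <- "st"
  out[AR > 7] <- "t"
  out
}

measurement_cols <- c("cell_id", "pair_id", "homolog", "short_arm_um",
                      "long_arm_um", "satellite_um", "satellite_arm")

#' Read a chromosome measurement table
#'
#' The CSV dialect is UTF-8 with header
#' \code{cell_id,pair_id,homolog,short_arm_um,long_arm_um,satellite_um,satellite_arm}.
#' \code{satellite_arm} is one of \code{"short"}, \code{"long"}, \code{"none"}.
#'
#' @param path Path to a CSV file.
#' @return A data.frame of per-chromosome arm measurements.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(measurement_cols, names(df))
  if (length(missing))
    stop("measurement table lacks columns: ", paste(missing, collapse = ", "))
  df[measurement_cols]
}

#' Write a chromosome measurement table
#'
#' @param measurements Measurement data.frame (see \code{\link{read_measurements}}).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  utils::write.csv(measurements[measurement_cols], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

validate_measurements <- function(m) {
  missing <- setdiff(measurement_cols, names(m))
  if (length(missing))
    stop("measurement table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(m) == 0) stop("empty measurement table")
  bad <- !is.finite(m$short_arm_um) | !is.finite(m$long_arm_um) |
    m$short_arm_um <= 0 | m$long_arm_um <= 0
  if (any(bad))
    stop("non-positive arm length in rows: ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  if (!all(m$homolog %in% c(1L, 2L)))
    stop("homolog must be 1 or 2")
  if (!all(m$satellite_arm %in% c("short", "long", "none")))
    stop("satellite_arm must be 'short', 'long' or 'none'")
  # every pair must have both homologs in every cell
  tab <- table(m$cell_id, m$pair_id)
  if (any(tab != 2)) {   # exactly 2 rows per (cell, pair)
    idx <- which(tab != 2, arr.ind = TRUE)
    pairs <- apply(idx, 1, function(i)
      sprintf("(cell %s, pair %s)", rownames(tab)[i[1]], colnames(tab)[i[2]]))
    stop("missing/extra homolog rows at: ",
         paste(utils::head(pairs, 5), collapse = ", "))
  }
  invisible(m)
}

# swap arms so long_arm >= short_arm, keeping the satellite on its physical arm
orient_measurements <- function(m) {
  swap <- m$short_arm_um > m$long_arm_um
  if (any(swap)) {
    s <- m$short_arm_um[swap]
    m$short_arm_um[swap] <- m$long_arm_um[swap]
    m$long_arm_um[swap] <- s
    sa <- m$satellite_arm[swap]
    m$satellite_arm[swap] <- ifelse(sa == "short", "long",
                                    ifelse(sa == "long", "short", "none"))
  }
  m
}

#' Build a karyotype from per-cell chromosome measurements
#'
#' Aggregates per-chromosome arm measurements over metaphase cells and both
#' homologs into homolog-pair statistics: mean arm lengths, relative length
#' (RL, % of the haploid complement), arm ratio (AR), centromeric index (CI)
#' and Levan class. Pairs are renumbered in order of decreasing mean total
#' length (ties broken by lower AR, then original pair id). The total length
#' of the haploid complement (TCL, the karyotype length) is computed over the
#' \code{n_cells_for_tcl} most condensed cells, operationalized as the cells
#' with the smallest summed chromosome length.
#'
#' Satellite segments are recorded per pair but excluded from arm lengths
#' (the secondary constriction is treated as a marker, not part of the arm).
#'
#' @param measurements Measurement data.frame with columns
#'   \code{cell_id, pair_id, homolog, short_arm_um, long_arm_um,
#'   satellite_um, satellite_arm}.
#' @param species Species/accession label carried into reports.
#' @param n_cells_for_tcl Number of most-condensed cells used for TCL
#'   (defaults to all cells if fewer are available).
#' @return An object of class \code{"karyotype"}: a list with elements
#'   \code{species}, \code{pairs} (one row per renumbered homolog pair),
#'   \code{two_n}, \code{TCL}, \code{TCL_sd}, \code{formula},
#'   \code{chromosomes} (mean-cell arm lengths per homolog) and
#'   \code{n_cells}.
#' @examples
#' fix <- miscanthus_fixture()
#' k <- karyotype(fix$measurements, species = "synthetic")
#' k
#' summary(k)
#' @export
karyotype <- function(measurements, species = "unspecified",
                      n_cells_for_tcl = 5L) {
  m <- validate_measurements(as.data.frame(measurements))
  m <- orient_measurements(m)

  key <- factor(m$pair_id, levels = sort(unique(m$pair_id)))
  mean_short <- tapply(m$short_arm_um, key, mean)
  mean_long <- tapply(m$long_arm_um, key, mean)
  sat <- tapply(m$satellite_arm != "none", key, any)
  sat_arm <- tapply(m$satellite_arm, key, function(x) {
    x <- x[x != "none"]
    if (!length(x)) "none" else names(sort(table(x), decreasing = TRUE))[1]
  })
  sat_len <- tapply(ifelse(m$satellite_arm == "none", NA, m$satellite_um),
                    key, function(x) if (all(is.na(x))) 0 else mean(x, na.rm = TRUE))

  total <- mean_short + mean_long
  pairs <- data.frame(
    orig_pair_id = as.integer(levels(key)),
    mean_short = as.numeric(mean_short),
    mean_long = as.numeric(mean_long),
    total_len = as.numeric(total),
    AR = as.numeric(mean_long / mean_short),
    CI = as.numeric(100 * mean_short / total),
    sat = as.logical(sat),
    sat_arm = as.character(sat_arm),
    sat_len = as.numeric(sat_len),
    stringsAsFactors = FALSE
  )
  ord <- order(-pairs$total_len, pairs$AR, pairs$orig_pair_id)
  pairs <- pairs[ord, , drop = FALSE]
  pairs$pair_id <- seq_len(nrow(pairs))
  rownames(pairs) <- NULL
  pairs$RL <- 100 * pairs$total_len / sum(pairs$total_len)
  pairs$levan_type <- classify_levan(pairs$AR)
  pairs <- pairs[c("pair_id", "orig_pair_id", "mean_short", "mean_long",
                   "total_len", "RL", "AR", "CI", "levan_type",
                   "sat", "sat_arm", "sat_len")]

  # TCL over the most condensed (shortest-complement) cells
  cell_tot <- tapply(m$short_arm_um + m$long_arm_um, m$cell_id, sum) / 2
  n_sel <- min(n_cells_for_tcl, length(cell_tot))
  sel <- sort(names(sort(cell_tot)[seq_len(n_sel)]))
  tcl_cells <- cell_tot[sel]
  TCL <- mean(tcl_cells)
  TCL_sd <- if (n_sel > 1) stats::sd(tcl_cells) else NA_real_

  # mean cell: per (pair, homolog) arm means, for per-chromosome CI spread
  hkey <- interaction(m$pair_id, m$homolog, drop = TRUE)
  chrom <- data.frame(
    pair_id = as.integer(tapply(m$pair_id, hkey, unique)),
    homolog = as.integer(tapply(m$homolog, hkey, unique)),
    short = as.numeric(tapply(m$short_arm_um, hkey, mean)),
    long = as.numeric(tapply(m$long_arm_um, hkey, mean))
  )
  chrom$CI <- 100 * chrom$short / (chrom$short + chrom$long)

  k <- structure(list(
    species = species,
    pairs = pairs,
    two_n = 2L * nrow(pairs),
    TCL = as.numeric(TCL),
    TCL_sd = as.numeric(TCL_sd),
    tcl_cells = tcl_cells,
    chromosomes = chrom,
    n_cells = length(cell_tot),
    measurements = m
  ), class = "karyotype")
  k$formula <- karyotype_formula(k)
  k
}

#' Karyotype formula string
#'
#' Builds the conventional formula \code{"2n=2x=<2n>=<counts per Levan type>"}
#' with chromosome counts (two per homolog pair) listed in the order m, sm,
#' st, t, and \code{"(<k>SAT)"} appended to the count of a class containing
#' satellite pairs (k = number of SAT chromosomes).
#'
#' @param x A \code{karyotype} object (or its \code{pairs} data.frame).
#' @return A single string, e.g. \code{"2n=2x=38=34m(2SAT)+4sm"}.
#' @export
karyotype_formula <- function(x) {
  pairs <- if (inherits(x, "karyotype")) x$pairs else x
  types <- c("m", "sm", "st", "t")
  parts <- character(0)
  for (ty in types) {
    sel <- pairs$levan_type == ty
    if (!any(sel)) next
    n_chr <- 2L * sum(sel)
    n_sat <- 2L * sum(sel & pairs$sat)
    p <- paste0(n_chr, ty)
    if (n_sat > 0) p <- paste0(p, "(", n_sat, "SAT)")
    parts <- c(parts, p)
  }
  paste0("2n=2x=", 2L * nrow(pairs), "=", paste(parts, collapse = "+"))
}

#' Chromosome length ratio
#'
#' Ratio of the longest to the shortest chromosome of the complement
#' (pair mean total lengths). Scale-invariant: identical on um and RL scales.
#'
#' @param x A \code{karyotype} object.
#' @return A single number >= 1.
#' @export
length_ratio <- function(x) {
  stopifnot(inherits(x, "karyotype"))
  if (nrow(x$pairs) < 2) stop("length ratio needs at least two pairs")
  max(x$pairs$total_len) / min(x$pairs$total_len)
}

#' @export
print.karyotype <- function(x, ...) {
  cat("Karyotype of", x$species, "\n")
  cat("  2n =", x$two_n, " (", nrow(x$pairs), "homolog pairs,",
      x$n_cells, "cells )\n")
  cat("  formula:", x$formula, "\n")
  cat(sprintf("  TCL: %.2f um%s\n", x$TCL,
              if (is.na(x$TCL_sd)) "" else sprintf(" +/- %.2f", x$TCL_sd)))
  cat(sprintf("  RL range: %.2f-%.2f %%   length ratio: %.2f\n",
              min(x$pairs$RL), max(x$pairs$RL),
              max(x$pairs$total_len) / min(x$pairs$total_len)))
  invisible(x)
}

#' @export
coef.karyotype <- function(object, ...) {
  object$pairs
}

#' Serialize a karyotype report
#'
#' Writes the pair table as CSV, or the whole object (pairs, TCL, formula)
#' as JSON.
#'
#' @param x A \code{karyotype} object.
#' @param path Output path; format chosen by extension (.csv or .json).
#' @return \code{path}, invisibly.
#' @export
write_karyotype <- function(x, path) {
  stopifnot(inherits(x, "karyotype"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(
      species = x$species, two_n = x$two_n, TCL = x$TCL, TCL_sd = x$TCL_sd,
      formula = x$formula, pairs = x$pairs), path,
      auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(x$pairs, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
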