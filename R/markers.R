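marker_classes <- c("CPD_band", "DAPI_band", "rDNA_45S")
position_classes <- c("CEN", "PCEN", "PROX", "INT", "TER")

#' Construct a cytogenetic marker table
#'
#' Validates and normalizes a table of fluorochrome bands (CPD / DAPI) and
#' 45S rDNA FISH sites. Expected columns:
#' \describe{
#'   \item{marker_class}{\code{"CPD_band"}, \code{"DAPI_band"} or \code{"rDNA_45S"}}
#'   \item{pair_id}{homolog pair the marker sits on}
#'   \item{arm}{\code{"S"}, \code{"L"}, or \code{NA} for markers spanning the
#'     centromere (e.g. centromeric bands reported without an arm)}
#'   \item{position_class}{\code{"CEN"}, \code{"PCEN"}, \code{"PROX"},
#'     \code{"INT"} or \code{"TER"}}
#'   \item{band_len_um}{band length on (the first) homolog, um}
#'   \item{homologs_present}{\code{"both"} or \code{"one"}}
#'   \item{d_um}{distance of the site centre from the centromere (rDNA), um;
#'     \code{NA} for plain bands}
#' }
#' Optional columns: \code{band_len2_um} (second homolog's band length, for
#' heteromorphic bands) and \code{co_localized_with_45S} (logical).
#'
#' @param df A data.frame as above.
#' @return The validated data.frame, classed \code{"cyto_markers"}.
#' @export
cyto_markers <- function(df) {
  df <- as.data.frame(df)
  req <- c("marker_class", "pair_id", "arm", "position_class",
           "band_len_um", "homologs_present")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("marker table lacks columns: ", paste(missing, collapse = ", "))
  if (!all(df$marker_class %in% marker_classes))
    stop("marker_class must be one of: ", paste(marker_classes, collapse = ", "))
  if (!all(is.na(df$arm) | df$arm %in% c("S", "L")))
    stop("arm must be 'S', 'L' or NA")
  if (!all(df$position_class %in% position_classes))
    stop("position_class must be one of: ",
         paste(position_classes, collapse = ", "))
  if (any(df$band_len_um < 0, na.rm = TRUE)) stop("band_len_um must be >= 0")
  if (!all(df$homologs_present %in% c("both", "one")))
    stop("homologs_present must be 'both' or 'one'")
  if (is.null(df$d_um)) df$d_um <- NA_real_
  if (is.null(df$band_len2_um)) df$band_len2_um <- NA_real_
  class(df) <- c("cyto_markers", "data.frame")
  df
}

#' Read / write a marker CSV
#'
#' CSV dialect: header
#' \code{marker_class,pair_id,arm,position_class,band_len_um,homologs_present,d_um};
#' empty \code{arm} or \code{d_um} fields are NA.
#'
#' @param path CSV path.
#' @return \code{read_markers}: a \code{cyto_markers} table.
#' @export
read_markers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        na.strings = c("NA", ""))
  cyto_markers(df)
}

#' @rdname read_markers
#' @param markers A \code{cyto_markers} table.
#' @export
write_markers <- function(markers, path) {
  cols <- c("marker_class", "pair_id", "arm", "position_class",
            "band_len_um", "homologs_present", "d_um")
  utils::write.csv(as.data.frame(markers)[cols], path, row.names = FALSE,
                   quote = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' rDNA site position statistic di
#'
#' di = d * 100 / a: the distance of the centre of an rDNA FISH site from the
#' centromere, as a percentage of the length of the arm that carries it.
#' 0 is a centromeric site, 100 a terminal one. Scale-invariant in the
#' common unit of d and a.
#'
#' @param d Distance(s) of the site centre from the centromere.
#' @param a Length(s) of the corresponding arm (same unit as \code{d}).
#' @return Percentage(s) in [0, 100].
#' @examples
#' rdna_di(1.2, 4.7)  # 25.53...
#' @export
rdna_di <- function(d, a) {
  if (any(!is.finite(d)) || any(!is.finite(a))) stop("d and a must be finite")
  if (any(a <= 0)) stop("arm length must be positive")
  if (any(d < 0)) stop("d must be >= 0")
  if (any(d > a)) stop("site lies beyond the arm end (d > a)")
  d * 100 / a
}

#' Per-cell di summary
#'
#' Mean and sample SD of di over repeated (per-cell) measurements, with the
#' conventional "mean +/- SD" label.
#'
#' @param d Vector of per-cell distances from the centromere.
#' @param a Vector (or scalar) of the corresponding arm lengths.
#' @return List with \code{mean}, \code{sd}, \code{label}.
#' @export
rdna_di_summary <- function(d, a) {
  di <- rdna_di(d, a)
  m <- mean(di)
  s <- if (length(di) > 1) stats::sd(di) else NA_real_
  list(mean = m, sd = s,
       label = if (is.na(s)) sprintf("%.2f", m) else sprintf("%.2f ± %.2f", m, s))
}

#' Marker position code
#'
#' Formats a marker the way comparative cytogenetic tables list band and
#' rDNA positions: \code{"<pair><arm>-<position>"} (e.g. \code{"19S-PCEN"}),
#' or \code{"<pair> <position>"} when no arm applies (centromere-spanning
#' bands), with \code{" (one homologue)"} appended for heteromorphic markers
#' present on a single homolog, and \code{" (<di>\%)"} appended to rDNA sites
#' (di computed from \code{d_um} and the karyotype's mean arm length,
#' rounded to 2 decimals).
#'
#' @param marker One row of a \code{cyto_markers} table (data.frame of 1 row).
#' @param karyotype A \code{karyotype} object; required to resolve the arm
#'   length of rDNA sites and to validate the pair id.
#' @return A single string.
#' @export
marker_code <- function(marker, karyotype = NULL) {
  m <- as.data.frame(marker)
  stopifnot(nrow(m) == 1)
  if (!is.null(karyotype)) {
    stopifnot(inherits(karyotype, "karyotype"))
    if (!m$pair_id %in% karyotype$pairs$pair_id)
      stop("pair ", m$pair_id, " not present in the karyotype")
  }
  code <- if (is.na(m$arm)) {
    paste0(m$pair_id, " ", m$position_class)
  } else {
    paste0(m$pair_id, m$arm, "-", m$position_class)
  }
  if (m$marker_class == "rDNA_45S" && !is.na(m$d_um)) {
    if (is.null(karyotype))
      stop("a karyotype is needed to compute di for an rDNA site")
    p <- karyotype$pairs[karyotype$pairs$pair_id == m$pair_id, ]
    a <- if (identical(m$arm, "S")) p$mean_short else p$mean_long
    code <- sprintf("%s (%.2f%%)", code, rdna_di(m$d_um, a))
  }
  if (m$homologs_present == "one") code <- paste0(code, " (one homologue)")
  code
}

#' Parse a marker position code
#'
#' Inverse of \code{\link{marker_code}}: recovers pair id, arm, position
#' class, the one-homolog flag and (for rDNA codes) the printed di value.
#'
#' @param code A code string such as \code{"1L-PROX (25.53\%)"}.
#' @return List with \code{pair_id}, \code{arm}, \code{position_class},
#'   \code{homologs_present}, \code{di} (NA unless printed).
#' @export
parse_marker_code <- function(code) {
  one <- grepl("\\(one homologue\\)", code)
  s <- sub("\\s*\\(one homologue\\)", "", code)
  di <- NA_real_
  dm <- regmatches(s, regexec("\\(([0-9.]+)%\\)", s))[[1]]
  if (length(dm) == 2) {
    di <- as.numeric(dm[2])
    s <- sub("\\s*\\([0-9.]+%\\)", "", s)
  }
  s <- trimws(s)
  m <- regexec("^([0-9]+)([SL])-([A-Z]+)$", s)[[1]]
  if (m[1] != -1) {
    g <- regmatches(s, regexec("^([0-9]+)([SL])-([A-Z]+)$", s))[[1]]
    out <- list(pair_id = as.integer(g[2]), arm = g[3], position_class = g[4])
  } else {
    g <- regmatches(s, regexec("^([0-9]+) ([A-Z]+)$", s))[[1]]
    if (length(g) != 3) stop("unparseable marker code: ", code)
    out <- list(pair_id = as.integer(g[2]), arm = NA_character_,
                position_class = g[3])
  }
  if (!out$position_class %in% position_classes)
    stop("unknown position class in code: ", code)
  out$homologs_present <- if (one) "one" else "both"
  out$di <- di
  out
}

#' Band amount as a percentage of the karyotype length
#'
#' Total fluorochrome band length per marker class, expressed as a percentage
#' of the diploid karyotype length (2 x TCL). Each homolog contributes its
#' own band length: \code{band_len_um} twice for \code{homologs_present ==
#' "both"} (or \code{band_len_um + band_len2_um} when a second length is
#' given for a heteromorphic band), once for \code{"one"}.
#'
#' @param markers A \code{cyto_markers} table.
#' @param karyotype A \code{karyotype} object supplying TCL.
#' @return Named numeric vector, one percentage per marker class present.
#' @export
band_amount_percent <- function(markers, karyotype) {
  stopifnot(inherits(karyotype, "karyotype"))
  if (!is.finite(karyotype$TCL) || karyotype$TCL <= 0)
    stop("karyotype TCL must be positive")
  m <- as.data.frame(markers)
  if (nrow(m) == 0) return(stats::setNames(numeric(0), character(0)))
  per_marker <- ifelse(
    m$homologs_present == "one",
    m$band_len_um,
    ifelse(is.na(m$band_len2_um), 2 * m$band_len_um,
           m$band_len_um + m$band_len2_um))
  tapply(per_marker, m$marker_class, sum) / (2 * karyotype$TCL) * 100
}

#' Heterozygosity (heteromorphism) report for markers
#'
#' Flags markers present on a single homolog, or whose two homologs' band
#' sizes differ by more than \code{ratio_threshold}-fold (requires
#' \code{band_len2_um}).
#'
#' @param markers A \code{cyto_markers} table.
#' @param ratio_threshold Size-ratio threshold (> 1) beyond which a
#'   two-homolog band is called heteromorphic. Default 2.
#' @return The marker table with logical column \code{heterozygous} and
#'   numeric column \code{size_ratio} appended.
#' @export
heterozygosity_report <- function(markers, ratio_threshold = 2) {
  m <- as.data.frame(markers)
  ratio <- ifelse(is.na(m$band_len2_um) | m$band_len_um <= 0 | m$band_len2_um <= 0,
                  NA_real_,
                  pmax(m$band_len_um, m$band_len2_um) /
                    pmin(m$band_len_um, m$band_len2_um))
  m$size_ratio <- ratio
  m$heterozygous <- m$homologs_present == "one" |
    (!is.na(ratio) & ratio > ratio_threshold)
  m
}

#' Map a fractional arm position to a position class
#'
#' Deterministic helper for annotators: the fractional position of a marker
#' centre along its arm, measured from the centromere (0) to the telomere
#' (1), is binned into CEN (<= 0.05), PCEN (<= 0.15), PROX (<= 0.40),
#' INT (<= 0.85) and TER (> 0.85). Cutoffs are configurable.
#'
#' @param frac Fractional arm position(s) in [0, 1].
#' @param cutoffs Named numeric vector of upper bounds for CEN, PCEN, PROX,
#'   INT (TER takes the rest).
#' @return Character vector of position classes.
#' @export
position_class_of <- function(frac,
                              cutoffs = c(CEN = 0.05, PCEN = 0.15,
                                          PROX = 0.40, INT = 0.85)) {
  if (any(frac < 0 | frac > 1)) stop("fractional position must be in [0, 1]")
  stopifnot(identical(names(cutoffs), c("CEN", "PCEN", "PROX", "INT")))
  as.character(cut(frac, breaks = c(-Inf, cutoffs, Inf),
                   labels = c(names(cutoffs), "TER"), right = TRUE))
}
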