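BASES <- c("A", "C", "G", "T")

# normalize any alignment input to an uppercase character matrix with
# taxa in rows, "-" for gaps
as_alignment_matrix <- function(aln) {
  if (inherits(aln, "DNAbin")) aln <- as.character(as.matrix(aln))
  if (is.list(aln) && !is.data.frame(aln)) {
    len <- unique(lengths(aln))
    if (length(len) != 1) stop("ragged alignment: sequences differ in length")
    aln <- do.call(rbind, aln)
  }
  if (is.character(aln) && is.null(dim(aln))) {
    lens <- unique(nchar(aln))
    if (length(lens) != 1) stop("ragged alignment: sequences differ in length")
    nm <- names(aln)
    aln <- do.call(rbind, strsplit(aln, ""))
    rownames(aln) <- nm
  }
  if (!is.matrix(aln)) stop("cannot interpret alignment input")
  aln <- toupper(aln)
  aln[aln == "."] <- "-"
  aln
}

#' Read / write an aligned FASTA file
#'
#' Thin wrappers around ape's FASTA IO returning/accepting the package's
#' internal representation: an uppercase character matrix with one taxon per
#' row and \code{"-"} for gaps.
#'
#' @param path FASTA path.
#' @return \code{read_alignment}: a character matrix.
#' @export
read_alignment <- function(path) {
  as_alignment_matrix(ape::read.FASTA(path))
}

#' @rdname read_alignment
#' @param aln Alignment (character matrix, named character vector of strings,
#'   or \code{DNAbin}).
#' @export
write_alignment <- function(aln, path) {
  m <- as_alignment_matrix(aln)
  ape::write.FASTA(ape::as.DNAbin(tolower(m)), path)
  invisible(path)
}

#' GC content of a sequence
#'
#' 100 * (G + C) / (A + C + G + T). Gaps, N and ambiguity codes are excluded
#' from both numerator and denominator.
#'
#' @param seq A sequence: single string or character vector of bases.
#' @param region Optional 0-based half-open interval \code{c(start, end)} on
#'   the ungapped sequence.
#' @return GC percentage.
#' @export
gc_content <- function(seq, region = NULL) {
  if (length(seq) == 1 && nchar(seq[1]) > 1) seq <- strsplit(seq, "")[[1]]
  seq <- toupper(seq)
  seq <- seq[seq != "-" & seq != "."]
  if (!is.null(region)) {
    stopifnot(length(region) == 2, region[1] >= 0, region[2] <= length(seq),
              region[1] < region[2])
    seq <- seq[(region[1] + 1):region[2]]
  }
  seq <- seq[seq %in% BASES]
  if (!length(seq)) stop("no unambiguous bases in the (sub)sequence")
  100 * sum(seq %in% c("G", "C")) / length(seq)
}

#' Classify alignment columns
#'
#' Labels every column of a multiple alignment as one of
#' \code{gap_containing} (any gap in the column; such columns are excluded
#' from variability statistics, complete-deletion style),
#' \code{conserved}, \code{variable_singleton} (>= 2 distinct unambiguous
#' bases, but only one base occurs in >= 2 sequences) or
#' \code{variable_informative} (parsimony-informative: >= 2 distinct bases
#' each in >= 2 sequences). Ambiguity codes and N never count as states.
#'
#' For each variable column, substitution events are typed over the distinct
#' observed bases: one event per unordered base pair, A<->G and C<->T being
#' transitions and all other pairs transversions.
#'
#' @param aln Alignment (see \code{\link{read_alignment}}), >= 2 sequences.
#' @return Object of class \code{"site_classification"}: list with
#'   \code{labels} (per column), \code{transitions}/\code{transversions}
#'   (per column), and \code{counts} (totals: \code{n_variable},
#'   \code{n_informative}, \code{n_singleton}, \code{n_conserved},
#'   \code{n_gap}, \code{transitions}, \code{transversions}, \code{ratio}).
#' @export
classify_sites <- function(aln) {
  m <- as_alignment_matrix(aln)
  if (nrow(m) < 2) stop("need at least two sequences")
  nc <- ncol(m)
  labels <- character(nc)
  ts <- integer(nc)
  tv <- integer(nc)
  for (j in seq_len(nc)) {
    col <- m[, j]
    if (any(col == "-")) {
      labels[j] <- "gap_containing"
      next
    }
    col <- col[col %in% BASES]
    tab <- table(col)
    if (length(tab) < 2) {
      labels[j] <- "conserved"
      next
    }
    labels[j] <- if (sum(tab >= 2) >= 2) "variable_informative"
                 else "variable_singleton"
    bs <- names(tab)
    prs <- utils::combn(bs, 2, simplify = FALSE)
    for (p in prs) {
      if (setequal(p, c("A", "G")) || setequal(p, c("C", "T")))
        ts[j] <- ts[j] + 1L
      else
        tv[j] <- tv[j] + 1L
    }
  }
  counts <- list(
    n_variable = sum(labels %in% c("variable_singleton", "variable_informative")),
    n_informative = sum(labels == "variable_informative"),
    n_singleton = sum(labels == "variable_singleton"),
    n_conserved = sum(labels == "conserved"),
    n_gap = sum(labels == "gap_containing"),
    transitions = sum(ts),
    transversions = sum(tv),
    ratio = paste0(sum(ts), ":", sum(tv))
  )
  structure(list(labels = labels, transitions = ts, transversions = tv,
                 counts = counts),
            class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  with(x$counts, cat(sprintf(
    "Site classification over %d columns:\n  variable %d (informative %d, singleton %d), conserved %d, gap-containing %d\n  transitions %d, transversions %d (ratio %s)\n",
    length(x$labels), n_variable, n_informative, n_singleton,
    n_conserved, n_gap, transitions, transversions, ratio)))
  invisible(x)
}

#' Count indel events in an alignment
#'
#' An indel event is a maximal run of consecutive gap-containing columns
#' sharing an identical gap presence/absence pattern across sequences. A
#' two-column gap in one sequence counts once; the same single-column gap
#' shared by two sequences counts once; adjacent columns with different gap
#' patterns count as separate events.
#'
#' @param aln Alignment.
#' @return Integer event count.
#' @export
count_indels <- function(aln) {
  m <- as_alignment_matrix(aln)
  gap <- m == "-"
  pat <- apply(gap, 2, function(g) paste(as.integer(g), collapse = ""))
  zero <- paste(rep("0", nrow(m)), collapse = "")
  events <- 0L
  prev <- zero
  for (j in seq_along(pat)) {
    if (pat[j] != zero && pat[j] != prev) events <- events + 1L
    prev <- pat[j]
  }
  events
}

#' Transition / transversion totals
#'
#' Convenience totals over \code{\link{classify_sites}}: one event per
#' unordered pair of distinct bases per variable column.
#'
#' @param aln Alignment.
#' @return List with \code{transitions}, \code{transversions}, \code{ratio}
#'   (a \code{"ts:tv"} string).
#' @export
count_substitution_types <- function(aln) {
  cs <- classify_sites(aln)
  list(transitions = cs$counts$transitions,
       transversions = cs$counts$transversions,
       ratio = cs$counts$ratio)
}

#' Map an ungapped interval to alignment columns
#'
#' Given one aligned sequence and a 0-based half-open interval on its
#' ungapped coordinates, returns the 0-based half-open alignment-column
#' interval spanning those residues.
#'
#' @param seq One aligned sequence (string or character vector, with gaps).
#' @param start,end 0-based half-open ungapped interval.
#' @return \code{c(start, end)} on alignment columns (0-based half-open).
#' @export
ungapped_to_alignment <- function(seq, start, end) {
  if (length(seq) == 1 && nchar(seq[1]) > 1) seq <- strsplit(seq, "")[[1]]
  pos <- which(seq != "-" & seq != ".")
  if (end > length(pos) || start < 0 || start >= end)
    stop("interval outside the ungapped sequence")
  c(pos[start + 1] - 1L, pos[end])
}

#' Per-region alignment summary table
#'
#' Computes, for each annotated region (e.g. ITS1, 5.8S, ITS2) and for the
#' complete alignment, the statistics conventionally tabulated for
#' ITS1-5.8S-ITS2 data sets: ungapped length range, GC content range across
#' taxa, number of indel events, variable and parsimony-informative sites,
#' transitions, transversions and their ratio.
#'
#' @param aln Alignment.
#' @param regions data.frame with columns \code{region}, \code{start},
#'   \code{end} (0-based half-open alignment-column intervals).
#' @return data.frame with one row per region plus a \code{"complete"} row.
#' @export
region_table <- function(aln, regions) {
  m <- as_alignment_matrix(aln)
  stopifnot(all(c("region", "start", "end") %in% names(regions)))
  if (any(regions$start < 0) || any(regions$end > ncol(m)) ||
      any(regions$start >= regions$end))
    stop("region annotation outside the alignment")
  one <- function(name, cols) {
    sub <- m[, cols, drop = FALSE]
    lens <- apply(sub, 1, function(r) sum(r != "-"))
    gc <- apply(sub, 1, gc_content)
    cs <- classify_sites(sub)
    rng <- function(v, fmt) {
      lo <- min(v); hi <- max(v)
      if (isTRUE(all.equal(lo, hi))) sprintf(fmt, lo)
      else paste0(sprintf(fmt, lo), "-", sprintf(fmt, hi))
    }
    data.frame(
      region = name,
      length_range = rng(lens, "%d"),
      gc_range = rng(gc, "%.2f"),
      indels = count_indels(sub),
      variable_sites = cs$counts$n_variable,
      informative_sites = cs$counts$n_informative,
      transitions = cs$counts$transitions,
      transversions = cs$counts$transversions,
      ratio = cs$counts$ratio,
      stringsAsFactors = FALSE
    )
  }
  rows <- lapply(seq_len(nrow(regions)), function(i)
    one(regions$region[i], (regions$start[i] + 1):regions$end[i]))
  rows <- c(rows, list(one("complete", seq_len(ncol(m)))))
  do.call(rbind, rows)
}
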