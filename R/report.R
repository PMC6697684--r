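#' Per-species karyotype report
#'
#' Bundles everything a comparative karyotype table reports per species: one
#' row with the karyotype formula, TCL +/- SD, relative-length range, mean
#' CI +/- SD, A1, A2, As K%, AI and the Stebbins category, plus a
#' marker listing (code and per-class band amounts) when markers are given.
#'
#' @param karyotype A \code{karyotype} object.
#' @param indices Optional precomputed \code{\link{karyotype_indices}};
#'   computed from \code{karyotype} when NULL.
#' @param markers Optional \code{cyto_markers} table.
#' @return Object of class \code{"species_report"}: list with
#'   \code{species_row} (one-row data.frame) and \code{marker_table}
#'   (data.frame, possibly empty).
#' @export
species_report <- function(karyotype, indices = NULL, markers = NULL) {
  stopifnot(inherits(karyotype, "karyotype"))
  if (is.null(indices)) indices <- karyotype_indices(karyotype)
  stopifnot(inherits(indices, "karyotype_indices"))
  row <- data.frame(
    species = karyotype$species,
    KF = karyotype$formula,
    TCL = indices$TCL,
    TCL_sd = indices$TCL_sd,
    RRL = sprintf("%.2f~%.2f", indices$RRL_min, indices$RRL_max),
    CI_mean = indices$CI_mean,
    CI_sd = indices$CI_sd,
    A1 = indices$A1,
    A2 = indices$A2,
    AsK = indices$AsK,
    AI = indices$AI,
    stebbins = indices$stebbins,
    stringsAsFactors = FALSE
  )
  marker_table <- data.frame(marker_class = character(0), code = character(0),
                             amount_percent = numeric(0),
                             stringsAsFactors = FALSE)
  if (!is.null(markers) && nrow(as.data.frame(markers))) {
    m <- as.data.frame(markers)
    codes <- vapply(seq_len(nrow(m)), function(i)
      marker_code(m[i, ], karyotype), character(1))
    amounts <- band_amount_percent(markers, karyotype)
    marker_table <- data.frame(
      marker_class = m$marker_class,
      code = codes,
      amount_percent = as.numeric(amounts[m$marker_class]),
      stringsAsFactors = FALSE)
  }
  structure(list(species_row = row, marker_table = marker_table),
            class = "species_report")
}

#' @export
print.species_report <- function(x, ...) {
  cat("Species report:\n")
  print(x$species_row, row.names = FALSE)
  if (nrow(x$marker_table)) {
    cat("Markers:\n")
    print(x$marker_table, row.names = FALSE)
  }
  invisible(x)
}

#' Write / read a species report
#'
#' \code{write_species_report} serializes the report row (and marker table)
#' as CSV or, with a \code{.json} path, the whole report as JSON.
#' \code{read_species_report} reads the CSV row back; every reported number
#' is re-derivable from the serialized artifacts.
#'
#' @param report A \code{species_report}.
#' @param path Output path (.csv or .json). For CSV the marker table goes to
#'   \code{<path stem>_markers.csv} when non-empty.
#' @return \code{path}, invisibly.
#' @export
write_species_report <- function(report, path) {
  stopifnot(inherits(report, "species_report"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(species_row = report$species_row,
                              marker_table = report$marker_table),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(report$species_row, path, row.names = FALSE)
    if (nrow(report$marker_table))
      utils::write.csv(report$marker_table,
                       sub("\\.csv$", "_markers.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_species_report
#' @export
read_species_report <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    row <- as.data.frame(x$species_row, stringsAsFactors = FALSE)
    mt <- as.data.frame(x$marker_table, stringsAsFactors = FALSE)
    if (!nrow(mt)) mt <- data.frame(marker_class = character(0),
                                    code = character(0),
                                    amount_percent = numeric(0))
  } else {
    row <- utils::read.csv(path, stringsAsFactors = FALSE)
    mpath <- sub("\\.csv$", "_markers.csv", path)
    mt <- if (file.exists(mpath))
      utils::read.csv(mpath, stringsAsFactors = FALSE)
    else data.frame(marker_class = character(0), code = character(0),
                    amount_percent = numeric(0))
  }
  structure(list(species_row = row, marker_table = mt),
            class = "species_report")
}
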