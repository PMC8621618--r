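#' Threshold compartment intensities into presence calls
#'
#' A reporter is called present when its measured intensity is greater than
#' or equal to `presence_threshold` (the at-threshold case counts as
#' present; this boundary convention is fixed and recorded with the calls).
#'
#' @param intensities Numeric vector of 12 non-negative intensities in
#'   barcode order ([reporter_cols()]).
#' @param presence_threshold Intensity threshold, default 40.
#' @return Named logical vector of 12 presence calls with attributes
#'   `intensities` and `threshold`.
#' @examples
#' x <- stats::setNames(rep(0, 12), reporter_cols())
#' x["mko_nuc"] <- 120
#' call_presence(x)
#' @export
call_presence <- function(intensities, presence_threshold = 40) {
  if (length(intensities) != 12L) {
    abort("`intensities` must hold 12 values (6 XFPs x cyt/nuc).")
  }
  if (anyNA(intensities) || any(intensities < 0)) {
    abort("intensities must be non-negative and non-missing.")
  }
  calls <- intensities >= presence_threshold
  names(calls) <- reporter_cols()
  attr(calls, "intensities") <- stats::setNames(as.numeric(intensities),
                                                reporter_cols())
  attr(calls, "threshold") <- presence_threshold
  calls
}

#' Encode presence calls as the 12-digit color barcode
#'
#' Positions 1-6 form the cytoplasm block and positions 7-12 the nucleus
#' block; position i within a block holds the XFP digit (1 YFP, 2 mKO,
#' 3 mCerulean, 4 mCherry, 5 mT-Sapphire, 6 EGFP) when that reporter is
#' present, else 0. E.g. YFP in the cytoplasm, mKO in the nucleus and
#' mCherry in both encodes as `"100400 020400"` in display form.
#'
#' @param calls Logical vector of 12 presence calls in barcode order
#'   (e.g. from [call_presence()]).
#' @return 12-character barcode string (no separator; use
#'   [format_barcode()] for the spaced display form).
#' @examples
#' calls <- stats::setNames(rep(FALSE, 12), reporter_cols())
#' calls[c("yfp_cyt", "mcherry_cyt", "mko_nuc", "mcherry_nuc")] <- TRUE
#' format_barcode(encode_barcode(calls))
#' @export
encode_barcode <- function(calls) {
  if (length(calls) != 12L || !is.logical(c(calls))) {
    abort("`calls` must be 12 logical presence calls.")
  }
  if (!any(calls)) {
    abort("unlabeled cell: all 12 presence calls are FALSE.")
  }
  digits <- rep(1:6, 2L)
  paste(ifelse(calls, as.character(digits), "0"), collapse = "")
}

#' Decode a 12-digit barcode back into presence calls
#'
#' Inverse of [encode_barcode()]: `decode_barcode(encode_barcode(x))`
#' recovers `x` for every valid non-zero pattern.
#'
#' @param code Barcode string; 12 digits, optionally with a space between
#'   the cytoplasm and nucleus blocks.
#' @return Named logical vector of 12 presence calls.
#' @export
decode_barcode <- function(code) {
  stopifnot(length(code) == 1L, is.character(code))
  code <- gsub(" ", "", code, fixed = TRUE)
  if (!grepl("^[0-9]{12}$", code)) {
    abort("barcode must be 12 digits (optionally '123456 123456' form).")
  }
  digs <- as.integer(strsplit(code, "")[[1L]])
  expected <- rep(1:6, 2L)
  bad <- which(digs != 0L & digs != expected)
  if (length(bad) > 0L) {
    abort(sprintf("malformed barcode: position %d holds %d, expected 0 or %d.",
                  bad[1L], digs[bad[1L]], expected[bad[1L]]))
  }
  if (all(digs == 0L)) {
    abort("all-zero barcode: unlabeled cell.")
  }
  stats::setNames(digs != 0L, reporter_cols())
}

#' Display form of a barcode
#'
#' @param code 12-digit barcode string(s).
#' @return The same barcode(s) with a space between the cytoplasm and
#'   nucleus blocks, e.g. `"100400 020400"`.
#' @export
format_barcode <- function(code) {
  code <- gsub(" ", "", code, fixed = TRUE)
  paste(substr(code, 1L, 6L), substr(code, 7L, 12L))
}

#' Add barcode calls to a cell table
#'
#' Thresholds the 12 intensity columns of every cell and appends a
#' `barcode` column (12-digit string). Cells with no reporter at or above
#' the threshold get the all-zero barcode and are treated as unlabeled by
#' downstream clone calling.
#'
#' @param cells Cell table with the [reporter_cols()] intensity columns.
#' @param presence_threshold Intensity threshold, default 40.
#' @return `cells` with a `barcode` column added (replaced if present).
#' @export
add_barcodes <- function(cells, presence_threshold = 40) {
  cols <- reporter_cols()
  missing <- setdiff(cols, names(cells))
  if (length(missing) > 0L) {
    abort(paste0("cell table lacks intensity columns: ",
                 paste(missing, collapse = ", ")))
  }
  m <- as.matrix(cells[cols])
  if (anyNA(m) || any(m < 0)) abort("intensities must be non-negative.")
  pres <- m >= presence_threshold
  digit_chr <- as.character(rep(1:6, 2L))
  parts <- lapply(seq_len(12L), function(j) {
    ifelse(pres[, j], digit_chr[j], "0")
  })
  cells$barcode <- do.call(paste0, parts)
  cells
}

#' Barcode frequency table
#'
#' Counts each distinct color code over all labeled cells and reports its
#' fraction of the dataset. These fractions drive the rarity filter: only
#' codes below the rarity threshold are eligible to support a mixed-clone
#' call, guarding against barcode collisions between independent
#' progenitors.
#'
#' @param cells Cell table with a `barcode` column (see [add_barcodes()]),
#'   or a character vector of barcodes.
#' @param scope `"dataset"` (default) computes fractions over all labeled
#'   cells in the table; `"animal"` computes them within each `animal_id`.
#' @return Tibble with `barcode`, `count`, `fraction` (plus `animal_id`
#'   when `scope = "animal"`), sorted by decreasing count. Fractions sum to
#'   1 within each scope.
#' @export
barcode_frequency <- function(cells, scope = c("dataset", "animal")) {
  scope <- match.arg(scope)
  if (is.character(cells)) {
    cells <- tibble::tibble(barcode = cells)
    scope <- "dataset"
  }
  if (!"barcode" %in% names(cells)) {
    abort("no `barcode` column; run add_barcodes() first.")
  }
  labeled <- dplyr::filter(cells, .data$barcode != ZERO_BARCODE)
  if (nrow(labeled) == 0L) abort("no labeled cells to tabulate.")
  if (scope == "animal") {
    labeled |>
      dplyr::count(.data$animal_id, .data$barcode, name = "count") |>
      dplyr::group_by(.data$animal_id) |>
      dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$animal_id, dplyr::desc(.data$count))
  } else {
    labeled |>
      dplyr::count(.data$barcode, name = "count") |>
      dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
      dplyr::arrange(dplyr::desc(.data$count))
  }
}
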