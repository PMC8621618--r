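# Fixed digit <-> fluorescent-protein assignment used throughout:
# 1 = YFP, 2 = mKO, 3 = mCerulean, 4 = mCherry, 5 = mT-Sapphire, 6 = EGFP.
XFP_NAMES <- c("yfp", "mko", "mcerulean", "mcherry", "mtsapphire", "egfp")

COMPARTMENTS <- c("cyt", "nuc")

FATE_CLASSES <- c("Ast", "NG2", "OL", "NG2+OL", "Ast+NG2", "Ast+OL")
UNIFORM_CLASSES <- c("Ast", "NG2", "OL", "NG2+OL")
MIXED_CLASSES <- c("Ast+NG2", "Ast+OL")

REGIONS <- c("UL", "LL", "CC")
CELL_TYPES <- c("astrocyte", "NG2", "oligodendrocyte")

ZERO_BARCODE <- strrep("0", 12)

#' Reporter channel map
#'
#' The twelve reporters of the multicolor labeling scheme: six fluorescent
#' proteins (XFPs), each in a cytoplasmic and a nuclear form. The digit
#' assignment is fixed: 1 YFP, 2 mKO, 3 mCerulean, 4 mCherry, 5 mT-Sapphire,
#' 6 EGFP; 0 means absence of signal.
#'
#' @return A tibble with one row per reporter: `reporter` (column name used
#'   in cell tables, `<xfp>_<compartment>`), `xfp`, `digit` (1-6) and
#'   `compartment` (`"cyt"` or `"nuc"`). Rows are in barcode-position order:
#'   cytoplasm block (positions 1-6) then nucleus block (positions 7-12).
#' @examples
#' channel_map()
#' @export
channel_map <- function() {
  tibble::tibble(
    reporter = reporter_cols(),
    xfp = rep(XFP_NAMES, 2L),
    digit = rep(1:6, 2L),
    compartment = rep(COMPARTMENTS, each = 6L)
  )
}

#' Names of the twelve intensity columns
#'
#' @return Character vector of the 12 intensity column names in barcode
#'   order: `yfp_cyt` ... `egfp_cyt`, then `yfp_nuc` ... `egfp_nuc`.
#' @export
reporter_cols <- function() {
  c(paste0(XFP_NAMES, "_cyt"), paste0(XFP_NAMES, "_nuc"))
}
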