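## Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero (half-up for non-negative input)
#'
#' Base R's `round()` uses IEC 60559 banker's rounding; summary percentages
#' here follow the print convention where x.x5 rounds upward.
#'
#' @param x numeric vector (non-negative in all pipeline uses).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Natural ordering key for chromosome names
#'
#' Numbered chromosomes ("chr3", "3", "Chr03") sort numerically first;
#' non-numeric contigs follow, ordered lexicographically.
#'
#' @param chrom character vector of chromosome names.
#' @return integer ranks usable with `order()`.
#' @keywords internal
chrom_order_key <- function(chrom) {
  num <- suppressWarnings(as.numeric(sub("^[Cc]hr", "", chrom)))
  lev <- unique(chrom[order(is.na(num), num, chrom)])
  match(chrom, lev)
}

#' Numeric part of a chromosome name
#'
#' "chr3" -> "3"; names without a numeric part are returned stripped of a
#' leading "chr"/"Chr" only (used when composing gene aliases).
#' @keywords internal
chrom_number <- function(chrom) {
  x <- sub("^[Cc]hr", "", chrom)
  x
}

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}
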