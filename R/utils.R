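#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages here follow
#' the half-up convention used in the summary tables (e.g. 94.65 -> 94.7).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
validate_chrom_lengths <- function(chrom_lengths) {
  if (!is.numeric(chrom_lengths) || length(chrom_lengths) < 1)
    stop("chrom_lengths must be a non-empty named numeric vector")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be named by chromosome")
  if (anyDuplicated(names(chrom_lengths)))
    stop("duplicated chromosome names in chrom_lengths")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  chrom_lengths
}

#' @keywords internal
check_chroms <- function(chroms, chrom_lengths) {
  bad <- setdiff(unique(as.character(chroms)), names(chrom_lengths))
  if (length(bad) > 0)
    stop("chromosome(s) absent from the length table: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

# 0-based half-open intervals -> GRanges (1-based closed); seqlevels can be
# widened so two sets compare on a shared chromosome namespace
#' @keywords internal
intervals_to_gr <- function(df, seqlevels = NULL) {
  lv <- unique(c(seqlevels, as.character(df$chrom)))
  if (nrow(df) == 0 && length(lv) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = factor(as.character(df$chrom), levels = lv),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    seqlengths = stats::setNames(rep(NA_integer_, length(lv)), lv)
  )
}

# fragment/interval midpoints (floor of the arithmetic mean)
#' @keywords internal
interval_midpoints <- function(df) {
  as.integer((as.numeric(df$start) + as.numeric(df$end)) %/% 2)
}

#' @keywords internal
chrom_lengths_of <- function(x, chrom_lengths = NULL) {
  cl <- chrom_lengths %||% attr(x, "chrom_lengths")
  if (is.null(cl)) stop("chrom_lengths required (not attached to the object)")
  validate_chrom_lengths(cl)
}
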