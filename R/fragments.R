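## Fragment processing: validation, quality filtering, duplicate capping,
## replicate pooling. Filters follow the published order: quality first,
## then the per-locus duplicate cap, then pooling of replicates.

#' Filtering parameters
#'
#' @param min_quality minimum per-end read quality; records where either end
#'   has quality below this are discarded (default 30).
#' @param max_duplicates maximum records retained per identical
#'   (chrom, start, end, strand) locus (default 20).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(min_quality = 30, max_duplicates = 20) {
  stopifnot(min_quality >= 0, max_duplicates >= 0)
  structure(list(min_quality = as.integer(min_quality),
                 max_duplicates = as.integer(max_duplicates)),
            class = "filter_params")
}

#' @keywords internal
validate_fragments <- function(fragments, chrom_lengths = NULL) {
  req <- c("chrom", "start", "end", "strand", "q1", "q2")
  miss <- setdiff(req, names(fragments))
  if (length(miss) > 0)
    stop("fragment table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(fragments) == 0) return(invisible(TRUE))
  if (any(fragments$start < 0) || any(fragments$end <= fragments$start))
    stop("invalid fragment coordinates (need end > start >= 0)")
  if (any(fragments$q1 < 0) || any(fragments$q2 < 0))
    stop("negative quality scores")
  if (!all(fragments$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!is.null(chrom_lengths)) {
    check_chroms(fragments$chrom, chrom_lengths)
    if (any(fragments$end > chrom_lengths[fragments$chrom]))
      stop("fragment extends beyond its chromosome")
  }
  invisible(TRUE)
}

#' Discard fragments with a low-quality end read
#'
#' A record is kept only if both per-end quality scores are at or above
#' `min_quality`; a single low-quality end discards the record. Order is
#' preserved and the input is not mutated.
#'
#' @param fragments fragment data.frame.
#' @param params a [filter_params()].
#' @return filtered fragment data.frame.
#' @export
filter_by_quality <- function(fragments, params = filter_params()) {
  validate_fragments(fragments)
  keep <- fragments$q1 >= params$min_quality &
    fragments$q2 >= params$min_quality
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "chrom_lengths") <- attr(fragments, "chrom_lengths")
  out
}

#' Cap duplicate fragments per locus
#'
#' A locus is an exact (chrom, start, end, strand) tuple; at most
#' `max_duplicates` records are retained per locus, keeping the first-seen
#' records in input order.
#'
#' @param fragments fragment data.frame.
#' @param params a [filter_params()].
#' @return capped fragment data.frame.
#' @export
cap_duplicates <- function(fragments, params = filter_params()) {
  validate_fragments(fragments)
  if (nrow(fragments) == 0) return(fragments)
  key <- paste(fragments$chrom, fragments$start, fragments$end,
               fragments$strand, sep = "\r")
  occurrence <- stats::ave(seq_len(nrow(fragments)), key, FUN = seq_along)
  out <- fragments[occurrence <= params$max_duplicates, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "chrom_lengths") <- attr(fragments, "chrom_lengths")
  out
}

#' Pool replicate fragment sets
#'
#' Concatenates per-replicate fragment tables (each tagged by its
#' `replicate_id`); the pooled size is the sum of the inputs. Replicates
#' must agree on the chromosome-length table when one is attached.
#'
#' @param replicate_sets list of fragment data.frames.
#' @return pooled fragment data.frame.
#' @export
pool_replicates <- function(replicate_sets) {
  stopifnot(is.list(replicate_sets), length(replicate_sets) >= 1)
  cls <- lapply(replicate_sets, attr, "chrom_lengths")
  cls <- cls[!vapply(cls, is.null, logical(1))]
  if (length(cls) > 1) {
    for (i in seq_along(cls)[-1])
      if (!identical(cls[[1]], cls[[i]]))
        stop("replicates carry inconsistent chromosome-length tables")
  }
  for (s in replicate_sets) validate_fragments(s)
  cols <- c("chrom", "start", "end", "strand", "q1", "q2", "replicate_id")
  out <- do.call(rbind, lapply(replicate_sets, function(s) s[, cols]))
  rownames(out) <- NULL
  if (length(cls) > 0) attr(out, "chrom_lengths") <- cls[[1]]
  out
}

#' Run the standard fragment-processing pipeline
#'
#' Applies, per replicate, the quality filter then the duplicate cap, then
#' pools the replicates.
#'
#' @param replicate_sets list of fragment data.frames.
#' @param params a [filter_params()].
#' @return pooled, filtered fragment data.frame.
#' @export
process_fragments <- function(replicate_sets, params = filter_params()) {
  pool_replicates(lapply(replicate_sets, function(s)
    cap_duplicates(filter_by_quality(s, params), params)))
}
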