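## Exhaustive no-mismatch genomic scan for degenerate gapped consensus
## motifs, specialized to the Gal4 consensus CGG-N11-CCG.

#' Consensus pattern over the IUPAC alphabet
#'
#' A run syntax `"N{11}"` is expanded, so `"CGGN{11}CCG"` and
#' `"CGGNNNNNNNNNNNCCG"` are equivalent.
#'
#' @param pattern IUPAC string (A/C/G/T plus ambiguity codes incl. N).
#' @param name pattern name.
#' @return object of class `consensus_pattern`.
#' @export
consensus_pattern <- function(pattern, name = "consensus") {
  pattern <- toupper(pattern)
  while (grepl("\\{", pattern)) {
    m <- regmatches(pattern, regexpr("([A-Z])\\{(\\d+)\\}", pattern))[1]
    sym <- substr(m, 1, 1)
    n <- as.integer(gsub("[^0-9]", "", m))
    pattern <- sub("([A-Z])\\{(\\d+)\\}", strrep(sym, n), pattern)
  }
  chars <- strsplit(pattern, "")[[1]]
  valid <- names(Biostrings::IUPAC_CODE_MAP)
  if (length(chars) < 1 || !all(chars %in% valid))
    stop("pattern must be a non-empty IUPAC string")
  structure(list(pattern = pattern, name = name,
                 length = length(chars)), class = "consensus_pattern")
}

#' The Gal4 binding consensus CGG-N11-CCG
#'
#' 17-bp gapped consensus recognized by the yeast Gal4 DNA-binding domain;
#' as a pattern it equals its own reverse complement, so a forward-strand
#' scan is strand-complete.
#'
#' @return a [consensus_pattern()].
#' @export
gal4_consensus <- function() consensus_pattern("CGGN{11}CCG", name = "Gal4")

#' Reverse complement of an IUPAC sequence
#'
#' @param sequence character string (IUPAC alphabet).
#' @return reverse-complemented character string.
#' @export
reverse_complement <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Exhaustive consensus scan of a genome
#'
#' Reports every forward-strand interval matching the pattern exactly, with
#' no mismatches. Degenerate pattern positions (e.g. N) match unambiguous
#' bases A/C/G/T only; no pattern position matches an ambiguous genome base
#' (such as N in unsequenced assembly gaps), so every reported site rests on
#' unambiguous sequence evidence. Overlapping occurrences are all reported;
#' each interval is reported once (for a reverse-complement-palindromic
#' pattern like Gal4 this counts sites, not strand events). Matching is
#' case-insensitive.
#'
#' @param genome named `Biostrings::DNAStringSet` (or a single character
#'   string, treated as one chromosome named "seq").
#' @param pattern a [consensus_pattern()] (default: Gal4).
#' @return data.frame (chrom, start, end, name), 0-based half-open, sorted
#'   by (chrom, start).
#' @export
scan_consensus <- function(genome, pattern = gal4_consensus()) {
  stopifnot(inherits(pattern, "consensus_pattern"))
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(stats::setNames(toupper(genome),
                                                       "seq"))
  if (length(genome) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  pat <- Biostrings::DNAString(pattern$pattern)
  res <- list()
  for (i in seq_along(genome)) {
    subject <- genome[[i]]
    if (length(subject) < pattern$length) next
    m <- Biostrings::matchPattern(pat, subject,
                                  fixed = c(pattern = FALSE, subject = TRUE))
    if (length(m) == 0) next
    # drop matches resting on ambiguous genome bases (N etc.)
    hit <- Biostrings::extractAt(subject, IRanges::ranges(m))
    acgt <- Biostrings::letterFrequency(hit, letters = "ACGT")[, 1]
    ok <- acgt == pattern$length
    if (!any(ok)) next
    res[[names(genome)[i]]] <- data.frame(
      chrom = names(genome)[i],
      start = BiocGenerics::start(m)[ok] - 1L,
      end = BiocGenerics::end(m)[ok],
      name = pattern$name, stringsAsFactors = FALSE)
  }
  if (length(res) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Expected consensus match count under an i.i.d. base model
#'
#' Sums, over all start positions, the product of per-position symbol
#' probabilities; the analytic null for match counts on i.i.d. random
#' sequence.
#'
#' @param genome_length total sequence length in bp (one chromosome; for
#'   several, sum the per-chromosome values).
#' @param pattern a [consensus_pattern()].
#' @param base_probs named numeric vector of A/C/G/T probabilities summing
#'   to 1.
#' @return expected number of matches (float).
#' @export
expected_match_count <- function(genome_length, pattern = gal4_consensus(),
                                 base_probs = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25)) {
  stopifnot(inherits(pattern, "consensus_pattern"))
  if (any(base_probs < 0) || abs(sum(base_probs) - 1) > 1e-8)
    stop("base_probs must be non-negative and sum to 1")
  if (!all(c("A", "C", "G", "T") %in% names(base_probs)))
    stop("base_probs must be named A/C/G/T")
  chars <- strsplit(pattern$pattern, "")[[1]]
  per_pos <- vapply(chars, function(ch) {
    members <- strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]]
    sum(base_probs[members])
  }, numeric(1))
  n_pos <- genome_length - pattern$length + 1
  if (n_pos <= 0) return(0)
  n_pos * prod(per_pos)
}
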