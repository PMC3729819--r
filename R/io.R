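#' Read ssDNA fragment records
#'
#' Fragments are stored as headerless 8-column TSV
#' (chrom, start, end, name, score, strand, q1, q2), coordinates 0-based
#' half-open; `name` carries the replicate tag. Lines starting with '#'
#' are ignored.
#'
#' @param path file path.
#' @param chrom_lengths optional named vector; when given, records are
#'   validated against it and it is attached to the result.
#' @return data.frame with columns chrom, start, end, strand, q1, q2,
#'   replicate_id.
#' @export
read_fragments <- function(path, chrom_lengths = NULL) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "q1", "q2"))
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    strand = df$strand, q1 = df$q1, q2 = df$q2,
                    replicate_id = as.character(df$name),
                    stringsAsFactors = FALSE)
  validate_fragments(out, chrom_lengths)
  if (!is.null(chrom_lengths))
    attr(out, "chrom_lengths") <- validate_chrom_lengths(chrom_lengths)
  out
}

#' Write ssDNA fragment records
#'
#' @param fragments fragment data.frame (see [read_fragments()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fragments <- function(fragments, path) {
  out <- data.frame(fragments$chrom, fragments$start, fragments$end,
                    fragments$replicate_id %||% ".", 0L, fragments$strand,
                    fragments$q1, fragments$q2)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED interval file
#'
#' Accepts BED3/BED4/BED6 (and wider); extra columns are kept with generic
#' names. Coordinates are 0-based half-open, as in BED.
#'
#' @param path file path.
#' @return data.frame with at least chrom, start, end.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  base <- c("chrom", "start", "end", "name", "score", "strand")
  n <- ncol(df)
  names(df) <- if (n <= 6) base[seq_len(n)] else
    c(base, paste0("V", seq_len(n - 6)))
  df
}

#' Write intervals as BED
#'
#' @param df data.frame with chrom, start, end and optionally name, score,
#'   strand.
#' @param path output path.
#' @param extra character vector of extra column names to append after the
#'   first six.
#' @return invisibly, `path`.
#' @export
write_bed <- function(df, path, extra = character()) {
  out <- data.frame(df$chrom, df$start, df$end,
                    df$name %||% ".",
                    df$score %||% 0,
                    df$strand %||% ".")
  for (col in extra) out[[col]] <- df[[col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a genome as FASTA
#'
#' @param genome named `Biostrings::DNAStringSet`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, filepath = path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA path.
#' @return named `Biostrings::DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
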