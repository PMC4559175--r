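#' Contiguity statistics for an assembly or scaffolding result
#'
#' Standard assembly evaluation metrics:
#' * N50 — the fragment size over which the sum of size-sorted fragment
#'   sizes reaches 50 % of the assembly total;
#' * LG50 / LG75 — the minimal number of fragments needed to cover 50 % /
#'   75 % of the reference genome length;
#' * genome coverage — (sum of fragment lengths - number of Ns) /
#'   reference length x 100.
#'
#' @param fragments The assembly fragments (scaffolds plus unscaffolded
#'   contigs): a `DNAStringSet`, a character vector of sequences, a FASTA
#'   path, or a numeric vector of lengths (in which case Ns count as 0).
#' @param reference_length Length of the reference genome in bp.
#' @param n_unscaffolded Optional count of unscaffolded contigs among the
#'   fragments, echoed into the report.
#' @return A list of class `sm_contiguity`: `fragment_count`,
#'   `unscaffolded`, `fragments_ge_10kb`, `max_size`, `n50`, `lg50`,
#'   `lg75`, `total_ns`, `genome_coverage_pct`.
#' @export
contiguity_stats <- function(fragments, reference_length,
                             n_unscaffolded = NA_integer_) {
  stopifnot(reference_length > 0)
  if (is.character(fragments) && length(fragments) == 1 &&
      file.exists(fragments))
    fragments <- Biostrings::readDNAStringSet(fragments)
  if (is.character(fragments))
    fragments <- Biostrings::DNAStringSet(fragments)
  if (is(fragments, "DNAStringSet")) {
    lens <- Biostrings::width(fragments)
    ns <- sum(Biostrings::vcountPattern("N", fragments))
  } else {
    lens <- as.numeric(fragments)
    ns <- 0L
  }
  if (length(lens) == 0) {
    warning("empty fragment set")
    res <- list(fragment_count = 0L, unscaffolded = n_unscaffolded,
                fragments_ge_10kb = 0L, max_size = 0, n50 = 0, lg50 = NA,
                lg75 = NA, total_ns = 0L, genome_coverage_pct = 0)
    class(res) <- "sm_contiguity"
    return(res)
  }
  lens <- sort(lens, decreasing = TRUE)
  cum <- cumsum(lens)
  n50 <- lens[which(cum >= sum(lens) / 2)[1]]
  lg <- function(frac) {
    need <- frac * reference_length
    i <- which(cum >= need)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  res <- list(
    fragment_count = length(lens),
    unscaffolded = n_unscaffolded,
    fragments_ge_10kb = sum(lens >= 10000),
    max_size = lens[1],
    n50 = n50,
    lg50 = lg(0.5),
    lg75 = lg(0.75),
    total_ns = as.integer(ns),
    genome_coverage_pct = (sum(lens) - ns) / reference_length * 100)
  class(res) <- "sm_contiguity"
  res
}

#' @export
print.sm_contiguity <- function(x, ...) {
  cat("contiguity statistics\n")
  cat(sprintf("  fragments: %d (>=10 kbp: %d; unscaffolded: %s)\n",
              x$fragment_count, x$fragments_ge_10kb,
              format(x$unscaffolded)))
  cat(sprintf("  max size: %s bp, N50: %s bp\n",
              format(x$max_size, big.mark = ","),
              format(x$n50, big.mark = ",")))
  cat(sprintf("  LG50: %s, LG75: %s\n", format(x$lg50), format(x$lg75)))
  cat(sprintf("  Ns: %d, genome coverage: %.2f %%\n", x$total_ns,
              x$genome_coverage_pct))
  invisible(x)
}
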