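#' Build the weight-position matrix from read alignments
#'
#' Counts, at every position of the assembled genome, the A/C/G/T bases
#' observed in the reads aligned there (match/mismatch columns only;
#' insertions, deletions and clipped bases contribute nothing). Both mates
#' of a pair are counted independently. The genome must be linear(ized):
#' alignments are expected to lie within the sequence.
#'
#' @param genome A `DNAString`/`DNAStringSet` of length one, or a
#'   single-sequence FASTA path.
#' @param alignments Path to a SAM (or BAM) file of reads mapped onto
#'   `genome`.
#' @return An object of class `sm_weight_matrix`: a list with `counts`
#'   (4 x L integer matrix, rows A/C/G/T) and `depth` (length-L integer
#'   vector, the column sums).
#' @export
build_weight_matrix <- function(genome, alignments) {
  genome <- as_single_dna(genome)
  L <- length(genome)
  bam <- local_sam_as_bam(alignments)
  pp <- Rsamtools::PileupParam(
    max_depth = 100000L, min_base_quality = 0L, min_mapq = 0L,
    min_nucleotide_depth = 1L, min_minor_allele_depth = 0L,
    distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE, include_deletions = FALSE,
    include_insertions = FALSE)
  pu <- Rsamtools::pileup(bam, pileupParam = pp)
  if (nrow(pu) && max(pu$pos) > L)
    stop("alignments extend beyond the genome end (position ",
         max(pu$pos), " > length ", L, ")")
  counts <- matrix(0L, nrow = 4, ncol = L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pu <- pu[pu$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
  if (nrow(pu)) {
    idx <- cbind(match(as.character(pu$nucleotide), rownames(counts)),
                 pu$pos)
    counts[idx] <- counts[idx] + pu$count
  }
  structure(list(counts = counts, depth = colSums(counts)),
            class = "sm_weight_matrix")
}

as_single_dna <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is(genome, "DNAStringSet")) {
    if (length(genome) != 1)
      stop("expected a single genome sequence, got ", length(genome))
    genome <- genome[[1]]
  }
  if (is.character(genome)) genome <- Biostrings::DNAString(genome)
  genome
}

#' @export
print.sm_weight_matrix <- function(x, ...) {
  cat(sprintf("weight-position matrix: %d positions, mean depth %.1f\n",
              ncol(x$counts), mean(x$depth)))
  invisible(x)
}

#' Correct polymorphisms by per-position base majority
#'
#' A position is corrected to base b when b differs from the assembled base
#' and more than 50 % of the reads covering the position show b. A
#' position is flagged as ambiguous — and never corrected — when the two
#' most abundant bases are equally frequent, when no base exceeds 50 %, or
#' when the depth is below `min_depth`. Substitutions only: the output
#' genome has the same length as the input.
#'
#' @param genome A `DNAString`/`DNAStringSet`(1)/character/FASTA path.
#' @param matrix An `sm_weight_matrix` from [build_weight_matrix()].
#' @param min_depth Depth below which a covered position is flagged
#'   (default 5). Zero-depth positions are left untouched and unflagged
#'   (no evidence either way).
#' @return A list: `genome` (corrected `DNAString`), `corrections`
#'   (data.frame `pos`, `from`, `to`, `depth`), `flagged` (data.frame
#'   `pos`, `A`, `C`, `G`, `T`, `depth`, `reason`).
#' @export
correct_polymorphisms <- function(genome, matrix, min_depth = 5) {
  genome <- as_single_dna(genome)
  L <- length(genome)
  if (ncol(matrix$counts) != L)
    stop("weight matrix has ", ncol(matrix$counts),
         " positions but the genome has ", L)
  counts <- matrix$counts
  depth <- matrix$depth
  bases <- rownames(counts)

  top_idx <- max.col(t(counts), ties.method = "first")
  top_n <- counts[cbind(top_idx, seq_len(L))]
  second_n <- apply(counts, 2, function(v) sort(v, decreasing = TRUE)[2])

  covered <- depth > 0
  tie <- covered & (top_n == second_n) & (top_n > 0)
  no_majority <- covered & (top_n / pmax(depth, 1) <= 0.5)
  low <- covered & (depth < min_depth)
  flagged <- tie | no_majority | low
  reason <- rep(NA_character_, L)
  reason[no_majority] <- "no_majority"
  reason[tie] <- "tie"
  reason[low] <- "low_depth"   # low depth dominates the report

  cur <- strsplit(as.character(genome), "")[[1]]
  majority <- covered & !flagged
  to_fix <- which(majority & bases[top_idx] != cur)
  new <- cur
  new[to_fix] <- bases[top_idx[to_fix]]

  fl <- which(flagged)
  list(
    genome = Biostrings::DNAString(paste(new, collapse = "")),
    corrections = data.frame(pos = to_fix, from = cur[to_fix],
                             to = new[to_fix], depth = depth[to_fix],
                             stringsAsFactors = FALSE),
    flagged = data.frame(pos = fl,
                         A = counts["A", fl], C = counts["C", fl],
                         G = counts["G", fl], T = counts["T", fl],
                         depth = depth[fl], reason = reason[fl],
                         stringsAsFactors = FALSE))
}

#' Write the flagged-positions report
#'
#' @param polished The list returned by [correct_polymorphisms()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_flagged_positions <- function(polished, path) {
  utils::write.table(polished$flagged, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Scan read depth for coverage anomalies
#'
#' Advisory report on sliding-window median depth: windows below
#' `low_factor` times the genome-wide median suggest an intra-contig
#' chimera (reads refuse to span the false join), windows above
#' `high_factor` times the median suggest collapsed repeats.
#'
#' @param matrix An `sm_weight_matrix`.
#' @param window Window size in bp (default 500).
#' @param low_factor,high_factor Flagging thresholds relative to the
#'   genome-wide median depth (defaults 0.5 and 1.5).
#' @return A data.frame `window_start`, `window_end`, `median_depth`,
#'   `flag` (`low`, `high` or `ok`).
#' @export
scan_coverage_anomalies <- function(matrix, window = 500,
                                    low_factor = 0.5, high_factor = 1.5) {
  depth <- matrix$depth
  L <- length(depth)
  gw <- stats::median(depth)
  starts <- seq(1L, L, by = window)
  med <- vapply(starts, function(s)
    stats::median(depth[s:min(L, s + window - 1L)]), numeric(1))
  flag <- rep("ok", length(starts))
  flag[med < low_factor * gw] <- "low"
  flag[med > high_factor * gw] <- "high"
  data.frame(window_start = starts,
             window_end = pmin(L, starts + window - 1L),
             median_depth = med, flag = flag, stringsAsFactors = FALSE)
}
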