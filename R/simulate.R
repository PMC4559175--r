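#' Specification for a synthetic mate-pair scaffolding dataset
#'
#' Describes a small circular (or linear) genome with optional planted
#' collapsed repeats and chimeric contigs, an assembly of it into contigs,
#' and a mate-pair library with a bimodal insert-size mixture (a main
#' kb-scale population plus an optional short-insert contaminant
#' population). The defaults emulate a prokaryotic mate-pair project shrunk
#' to a 24 kb genome so that a full pipeline run takes seconds: 8 contigs
#' of ~3 kb, 101 bp reads, ~800-fold coverage, a main insert population of
#' mean 1000 bp (sd 100) with 10 % short-insert contamination at 300 bp
#' (sd 30), and mild multiplicative coverage noise.
#'
#' @param genome_length Genome length in bp.
#' @param circular Whether the genome is circular.
#' @param n_contigs Number of unique-sequence contigs the genome is broken
#'   into.
#' @param segment_lengths Optional explicit lengths of the unique segments
#'   (overrides the random even-ish split; must sum to the genome length
#'   minus the planted repeat bases).
#' @param repeats Optional data.frame with columns `length` and `copies`:
#'   each row plants one repeat family whose copies are collapsed into a
#'   single consensus contig at multiplied coverage.
#' @param n_chimerae Number of chimeric contigs to inject, each fusing two
#'   non-adjacent unique segments.
#' @param read_length Read length in bp.
#' @param n_pairs Number of mate pairs to draw.
#' @param small_frac Fraction of pairs drawn from the short-insert
#'   population (0 disables it).
#' @param small_mean,small_sd Short-insert population mean and sd (bp).
#' @param main_mean,main_sd Main insert population mean and sd (bp).
#' @param base_coverage Single-copy fold-coverage reported in the contig
#'   info table.
#' @param coverage_noise_sd Multiplicative (lognormal-style) noise sd on
#'   reported coverages.
#' @param mismatch_rate Fraction of mappings given 1-3 sprinkled
#'   mismatches.
#' @param rng_seed Seed for all randomness in the generator.
#' @return A list of class `sm_sim_spec`.
#' @export
simulation_spec <- function(genome_length = 24000, circular = TRUE,
                            n_contigs = 8, segment_lengths = NULL,
                            repeats = NULL, n_chimerae = 0,
                            read_length = 101, n_pairs = 6000,
                            small_frac = 0.1, small_mean = 300,
                            small_sd = 30, main_mean = 1000, main_sd = 100,
                            base_coverage = 800, coverage_noise_sd = 0.05,
                            mismatch_rate = 0, rng_seed = 1L) {
  spec <- list(genome_length = genome_length, circular = circular,
               n_contigs = if (is.null(segment_lengths)) n_contigs else
                 length(segment_lengths),
               segment_lengths = segment_lengths, repeats = repeats,
               n_chimerae = n_chimerae, read_length = read_length,
               n_pairs = n_pairs, small_frac = small_frac,
               small_mean = small_mean, small_sd = small_sd,
               main_mean = main_mean, main_sd = main_sd,
               base_coverage = base_coverage,
               coverage_noise_sd = coverage_noise_sd,
               mismatch_rate = mismatch_rate,
               rng_seed = as.integer(rng_seed))
  stopifnot(genome_length > 0, n_contigs >= 1, read_length > 0,
            n_pairs >= 0, small_frac >= 0, small_frac <= 1,
            main_mean > 2 * read_length)
  if (!is.null(repeats)) {
    stopifnot(all(c("length", "copies") %in% names(repeats)),
              all(repeats$length > 0), all(repeats$copies >= 2))
    if (sum(repeats$length * repeats$copies) >= genome_length)
      stop("planted repeats exceed the genome length")
  }
  class(spec) <- "sm_sim_spec"
  spec
}

#' Insert-size bounds implied by a simulation spec
#'
#' The bounds a user would read off the insert-size histogram: three
#' standard deviations above each population mean (0 for the small bound
#' when the short-insert population is absent).
#'
#' @param spec An `sm_sim_spec`.
#' @return A list `small_insert_upper`, `main_insert_upper`.
#' @export
spec_insert_bounds <- function(spec) {
  list(small_insert_upper = if (spec$small_frac > 0)
    spec$small_mean + 3 * spec$small_sd else 0,
    main_insert_upper = spec$main_mean + 3 * spec$main_sd)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a mate-pair scaffolding dataset
#'
#' Builds a genome of unique segments with planted repeat copies between
#' them, emulates its assembly into contigs (one contig per unique
#' segment; each repeat family collapsed into one consensus contig at
#' multiplied coverage; optionally chimeric contigs fusing two non-adjacent
#' segments), then draws mate pairs from the insert mixture and maps them
#' analytically onto contig coordinates — a mate maps iff its interval
#' lies fully inside one segment instance, which is exactly the full-length
#' criterion an aligner would apply at contig boundaries.
#'
#' @param spec An [simulation_spec()] object.
#' @return A list of class `sm_simulation`:
#'   `genome` (DNAString), `sequences` (contig DNAStringSet),
#'   `contigs` (info data.frame), `mappings` (mapping data.frame),
#'   `truth` (list: `order` data.frame of the true contig walk around the
#'   genome, `copy_numbers`, `chimerae` with fusion breakpoints,
#'   `bounds` from [spec_insert_bounds()]), and `spec`.
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "sm_sim_spec"))
  set.seed(spec$rng_seed)
  rl <- spec$read_length

  # --- layout: unique segments with repeat copies at random junctions ---
  rep_families <- if (is.null(spec$repeats)) 0 else nrow(spec$repeats)
  rep_total <- if (rep_families) sum(spec$repeats$length *
                                       spec$repeats$copies) else 0
  unique_total <- spec$genome_length - rep_total
  if (!is.null(spec$segment_lengths)) {
    seg_len <- as.integer(spec$segment_lengths)
    if (sum(seg_len) != unique_total)
      stop("segment_lengths must sum to ", unique_total)
  } else {
    w <- stats::runif(spec$n_contigs, 0.8, 1.2)
    seg_len <- floor(unique_total * w / sum(w))
    seg_len[1] <- seg_len[1] + (unique_total - sum(seg_len))
  }
  if (any(seg_len < 2 * rl))
    stop("infeasible spec: a unique segment would be shorter than two reads")

  seg_ids <- sprintf("c%02d", seq_len(spec$n_contigs))
  seg_seq <- stats::setNames(
    as.list(vapply(seg_len, random_dna, character(1))), seg_ids)

  # each layout element: a unique segment or one copy of a repeat family
  layout <- data.frame(element = seg_ids, kind = "unique",
                       length = seg_len, stringsAsFactors = FALSE)
  rep_seq <- list()
  if (rep_families) {
    for (f in seq_len(rep_families)) {
      fid <- sprintf("r%02d", f)
      rep_seq[[fid]] <- random_dna(spec$repeats$length[f])
      # insert copies after distinct unique segments
      slots <- sample(seq_len(spec$n_contigs), spec$repeats$copies[f])
      for (s in sort(slots, decreasing = TRUE)) {
        at <- which(layout$element == seg_ids[s])
        layout <- rbind(layout[seq_len(at), ],
                        data.frame(element = fid, kind = "repeat",
                                   length = spec$repeats$length[f],
                                   stringsAsFactors = FALSE),
                        if (at < nrow(layout))
                          layout[(at + 1):nrow(layout), ])
      }
    }
  }
  layout$g_start <- cumsum(c(1, layout$length[-nrow(layout)]))
  layout$g_end <- layout$g_start + layout$length - 1L

  genome <- paste(
    vapply(seq_len(nrow(layout)), function(i) {
      e <- layout$element[i]
      if (layout$kind[i] == "unique") seg_seq[[e]] else rep_seq[[e]]
    }, character(1)), collapse = "")

  # --- contigs; chimera injection fuses two non-adjacent unique segments --
  noise <- function(n) exp(stats::rnorm(n, 0, spec$coverage_noise_sd))
  chimera_truth <- data.frame(contig_id = character(),
                              left = character(), right = character(),
                              breakpoint = integer(),
                              stringsAsFactors = FALSE)
  # contig of each layout element and the offset of the element within it
  layout$contig <- layout$element
  layout$offset <- 0L
  if (spec$n_chimerae > 0) {
    if (spec$n_chimerae * 2 + 1 > spec$n_contigs)
      stop("infeasible spec: not enough unique segments to fuse into ",
           spec$n_chimerae, " chimera(e)")
    # fuse segment pairs (i, i + n_contigs/2-ish) — guaranteed non-adjacent
    gap <- max(2L, spec$n_contigs %/% 2L)
    for (k in seq_len(spec$n_chimerae)) {
      a <- seg_ids[k]
      b <- seg_ids[((k - 1L + gap) %% spec$n_contigs) + 1L]
      cid <- paste0(a, b)
      la <- seg_len[match(a, seg_ids)]
      layout$contig[layout$element == a] <- cid
      layout$contig[layout$element == b] <- cid
      layout$offset[layout$element == b] <- la
      seg_seq[[cid]] <- paste0(seg_seq[[a]], seg_seq[[b]])
      chimera_truth <- rbind(chimera_truth, data.frame(
        contig_id = cid, left = a, right = b, breakpoint = la,
        stringsAsFactors = FALSE))
      seg_seq[[a]] <- seg_seq[[b]] <- NULL
    }
  }
  contig_ids <- unique(layout$contig)
  contig_len <- vapply(contig_ids, function(cid) {
    rows <- layout[layout$contig == cid, , drop = FALSE]
    max(rows$offset + rows$length)
  }, numeric(1))
  true_copies <- vapply(contig_ids, function(cid) {
    rows <- layout[layout$contig == cid, , drop = FALSE]
    if (rows$kind[1] == "repeat") nrow(rows) else 1L
  }, numeric(1))
  coverage <- spec$base_coverage * true_copies * noise(length(contig_ids))
  contigs <- data.frame(contig_id = contig_ids,
                        length = as.integer(contig_len),
                        coverage = round(coverage, 1),
                        stringsAsFactors = FALSE)
  sequences <- Biostrings::DNAStringSet(vapply(contig_ids, function(cid) {
    rows <- layout[layout$contig == cid, , drop = FALSE]
    if (rows$kind[1] == "repeat") rep_seq[[rows$element[1]]]
    else seg_seq[[cid]]
  }, character(1)))
  names(sequences) <- contig_ids

  # --- mate pairs, mapped analytically --------------------------------
  G <- spec$genome_length
  n <- spec$n_pairs
  is_small <- stats::runif(n) < spec$small_frac
  ins <- ifelse(is_small,
                stats::rnorm(n, spec$small_mean, spec$small_sd),
                stats::rnorm(n, spec$main_mean, spec$main_sd))
  ins <- pmax(rl, as.integer(round(ins)))
  u <- if (spec$circular) sample.int(G, n, replace = TRUE) else
    pmax(1L, sample.int(max(1L, G - max(ins)), n, replace = TRUE))
  read_id <- sprintf("p%06d", seq_len(n))

  wrap <- function(x) ((x - 1L) %% G) + 1L
  # a mate maps iff its (non-wrapping) interval lies inside one element;
  # layout tiles the genome, so findInterval on g_start locates it
  map_mate <- function(a, mate_no) {
    b <- a + rl - 1L
    i <- findInterval(a, layout$g_start)
    ok <- b <= G & b <= layout$g_end[i]
    data.frame(read_id = read_id, mate = mate_no,
               contig_id = layout$contig[i],
               start = as.integer(a - layout$g_start[i] + 1L +
                                    layout$offset[i]),
               stringsAsFactors = FALSE)[ok, , drop = FALSE]
  }
  mappings <- rbind(map_mate(wrap(u), 1L),
                    map_mate(wrap(u + ins - rl), 2L))
  mappings$end <- mappings$start + rl - 1L
  mappings$strand <- ifelse(mappings$mate == 1L, "+", "-")
  mappings$mismatches <- 0L
  mappings$full_length <- TRUE
  mappings <- mappings[order(mappings$read_id, mappings$mate), ,
                       drop = FALSE]
  rownames(mappings) <- NULL
  if (spec$mismatch_rate > 0 && nrow(mappings)) {
    hitn <- stats::runif(nrow(mappings)) < spec$mismatch_rate
    mappings$mismatches[hitn] <- sample(1:3, sum(hitn), replace = TRUE)
  }

  truth_order <- data.frame(position = seq_len(nrow(layout)),
                            contig_id = layout$contig,
                            element = layout$element,
                            orientation = "+",
                            g_start = layout$g_start,
                            g_end = layout$g_end,
                            stringsAsFactors = FALSE)
  structure(list(
    genome = Biostrings::DNAString(genome),
    sequences = sequences,
    contigs = contigs,
    mappings = mappings,
    truth = list(order = truth_order,
                 copy_numbers = data.frame(contig_id = contig_ids,
                                           copies = as.integer(true_copies),
                                           stringsAsFactors = FALSE),
                 chimerae = chimera_truth,
                 bounds = spec_insert_bounds(spec)),
    spec = spec), class = "sm_simulation")
}

#' Configuration matched to a simulated dataset
#'
#' Convenience: an [sm_config()] whose insert bounds are the ones implied
#' by the simulation spec.
#'
#' @param sim An `sm_simulation`.
#' @param ... Further arguments passed to [sm_config()].
#' @return An `sm_config` object.
#' @export
sim_config <- function(sim, ...) {
  b <- sim$truth$bounds
  sm_config(small_insert_upper = b$small_insert_upper,
            main_insert_upper = b$main_insert_upper,
            rng_seed = sim$spec$rng_seed, ...)
}

#' Write a simulated dataset to disk as pipeline input files
#'
#' @param sim An `sm_simulation`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    contigs_fasta = file.path(dir, "contigs.fasta"),
    contig_info = file.path(dir, "contig_info.tsv"),
    mappings = file.path(dir, "mp_mappings.tsv"),
    truth = file.path(dir, "truth_order.tsv"))
  Biostrings::writeXStringSet(sim$sequences, paths["contigs_fasta"],
                              width = 70)
  utils::write.table(
    sim$contigs[, c("contig_id", "coverage", "length")],
    paths["contig_info"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_mappings_tab7(sim$mappings, paths["mappings"])
  utils::write.table(sim$truth$order, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(paths)
}

#' Write mappings as a minimal SAM file
#'
#' Produces a valid SAM rendering of a mapping table: one record per mate,
#' proper pairing flags, `<n>M` CIGAR and an `NM` tag. Sequences are
#' omitted (`*`) unless `seqs` provides per-row forward-strand bases (as
#' needed for pileup-based polishing).
#'
#' @param mappings Mapping data.frame.
#' @param contigs Contig info data.frame (for `@SQ` header lines).
#' @param path Output SAM path.
#' @param seqs Optional character vector, one forward-strand sequence per
#'   mapping row.
#' @return `path`, invisibly.
#' @export
write_mappings_sam <- function(mappings, contigs, path, seqs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", contigs$contig_id,
                     contigs$length), con)
  if (nrow(mappings)) {
    flag <- 1L +
      ifelse(mappings$mate == 2L, 128L, 64L) +
      ifelse(mappings$strand == "-", 16L, 0L)
    cig <- sprintf("%dM", mappings$end - mappings$start + 1L)
    seq_field <- if (is.null(seqs)) "*" else seqs
    qual <- if (is.null(seqs)) "*" else
      vapply(nchar(seqs), function(w)
        paste(rep("I", w), collapse = ""), character(1))
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                       mappings$read_id, flag, mappings$contig_id,
                       mappings$start, cig, seq_field, qual,
                       mappings$mismatches), con)
  }
  invisible(path)
}
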