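# Small in-code fixture builders shared across the test files.

make_contigs <- function(ids, lengths, coverages = rep(100, length(ids))) {
  data.frame(contig_id = ids, length = as.integer(lengths),
             coverage = coverages, stringsAsFactors = FALSE)
}

make_mapping <- function(read_id, mate, contig_id, start, end,
                         strand = "+", mismatches = 0L,
                         full_length = TRUE) {
  data.frame(read_id = read_id, mate = as.integer(mate),
             contig_id = contig_id, start = as.integer(start),
             end = as.integer(end), strand = strand,
             mismatches = as.integer(mismatches),
             full_length = full_length, stringsAsFactors = FALSE)
}

# n synthetic clean links between end ea of a and end eb of b
make_links <- function(a, ea, b, eb, n, prefix = paste0(a, b)) {
  if (n == 0)
    return(data.frame(read_id = character(), contig_a = character(),
                      contig_b = character(), end_a = character(),
                      end_b = character(), dist_a = numeric(),
                      dist_b = numeric(), orient_a = character(),
                      orient_b = character(), pos_a = integer(),
                      pos_b = integer(), insert = integer(),
                      intra = logical(), stringsAsFactors = FALSE))
  data.frame(read_id = sprintf("%s_%03d", prefix, seq_len(n)),
             contig_a = a, contig_b = b, end_a = ea, end_b = eb,
             dist_a = 100, dist_b = 100,
             orient_a = "+", orient_b = "+", pos_a = 1L, pos_b = 1L,
             insert = NA_integer_, intra = FALSE,
             stringsAsFactors = FALSE)
}

# a mapping data.frame for one proper pair on (possibly two) contigs
make_pair <- function(read_id, c1, s1, e1, c2, s2, e2) {
  rbind(make_mapping(read_id, 1, c1, s1, e1, "+"),
        make_mapping(read_id, 2, c2, s2, e2, "-"))
}

default_cfg <- function(...) {
  sm_config(small_insert_upper = 390, main_insert_upper = 1300, ...)
}

# Build a SAM of error-free single-end reads tiling a genome string.
resequence_sam <- function(genome, coverage = 40, rl = 101, seed = 1) {
  set.seed(seed)
  G <- nchar(genome)
  n_reads <- ceiling(coverage * G / rl)
  starts <- sample(G - rl + 1L, n_reads, replace = TRUE)
  maps <- data.frame(read_id = sprintf("r%06d", seq_len(n_reads)),
                     mate = rep(1:2, length.out = n_reads),
                     contig_id = "genome", start = starts,
                     end = starts + rl - 1L, strand = "+",
                     mismatches = 0L, stringsAsFactors = FALSE)
  sam <- tempfile(fileext = ".sam")
  write_mappings_sam(maps, data.frame(contig_id = "genome", length = G),
                     sam, seqs = substring(genome, starts,
                                           starts + rl - 1L))
  sam
}

# arrangement (contig_id, orientation) of a single-scaffold map
map_arrangement <- function(map) {
  pl <- map$placements[order(map$placements$rank), ]
  data.frame(contig_id = pl$contig_id, orientation = pl$orientation,
             stringsAsFactors = FALSE)
}
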