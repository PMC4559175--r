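#' Read a mate-pair mapping table
#'
#' Two dialects are accepted: the 7-column tabulated format (read id, mate
#' index, contig id, start, end, strand, mismatches — column positions
#' configurable through `cfg$map_columns`) and SAM. With `dialect =
#' "auto"` the file is sniffed: a first line starting with `@` followed by
#' a SAM record, or an 11+-column layout with SAM flags, selects SAM.
#'
#' SAM records that are unmapped, secondary or supplementary are skipped.
#' Coordinates are 1-based inclusive in both dialects. An alignment is
#' "full length" when its CIGAR contains no soft or hard clipping;
#' mismatches come from the `NM` tag (NA when the tag is absent).
#'
#' @param path Path to the mapping file.
#' @param dialect One of `"auto"`, `"tab7"`, `"sam"`.
#' @param cfg An [sm_config()] object (7-column positions).
#' @return A data.frame of mate mappings with columns `read_id`, `mate`
#'   (1 or 2), `contig_id`, `start`, `end`, `strand`, `mismatches`,
#'   `full_length`.
#' @export
read_mapping_table <- function(path, dialect = c("auto", "tab7", "sam"),
                               cfg = sm_config()) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") dialect <- sniff_mapping_dialect(path)
  switch(dialect,
         tab7 = read_mappings_tab7(path, cfg),
         sam = read_mappings_sam(path))
}

sniff_mapping_dialect <- function(path) {
  head <- readLines(path, n = 50, warn = FALSE)
  head <- head[nzchar(trimws(head))]
  if (length(head) == 0) return("tab7")
  if (grepl("^@(HD|SQ|RG|PG|CO)\t", head[1])) return("sam")
  first_rec <- head[!startsWith(head, "@")][1]
  if (is.na(first_rec)) return("sam")
  fields <- strsplit(first_rec, "\t", fixed = TRUE)[[1]]
  if (length(fields) >= 11 &&
      !is.na(suppressWarnings(as.integer(fields[2]))) &&
      !is.na(suppressWarnings(as.integer(fields[4]))))
    return("sam")
  "tab7"
}

read_mappings_tab7 <- function(path, cfg) {
  raw <- read_table_lines(path)
  mc <- cfg$map_columns
  need <- max(mc)
  empty <- data.frame(read_id = character(), mate = integer(),
                      contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), full_length = logical(),
                      stringsAsFactors = FALSE)
  if (raw$nrow == 0) return(empty)
  bad <- which(raw$n_fields < need)
  if (length(bad))
    stop("mapping table ", path, ": line ", raw$lineno[bad[1]], " has ",
         raw$n_fields[bad[1]], " fields, need at least ", need)
  f <- raw$fields
  col <- function(i) vapply(f, `[`, character(1), i)
  df <- data.frame(
    read_id = col(mc[["read_id"]]),
    mate = suppressWarnings(as.integer(col(mc[["mate"]]))),
    contig_id = col(mc[["contig_id"]]),
    start = suppressWarnings(as.integer(col(mc[["start"]]))),
    end = suppressWarnings(as.integer(col(mc[["end"]]))),
    strand = col(mc[["strand"]]),
    mismatches = suppressWarnings(as.integer(col(mc[["mismatches"]]))),
    full_length = TRUE,
    stringsAsFactors = FALSE)
  if (anyNA(df$mate) || !all(df$mate %in% 1:2))
    stop("mapping table ", path, ": mate index must be 1 or 2")
  if (anyNA(df$start) || anyNA(df$end))
    stop("mapping table ", path, ": non-numeric start/end position")
  # tolerate 3'-to-5' coordinate pairs from aligners that report hit strand
  # by coordinate order
  flip <- df$end < df$start
  if (any(flip)) {
    tmp <- df$start[flip]
    df$start[flip] <- df$end[flip]
    df$end[flip] <- tmp
  }
  df$strand <- ifelse(df$strand %in% c("-", "minus", "R"), "-", "+")
  df
}

read_mappings_sam <- function(path) {
  bam <- local_sam_as_bam(path)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "cigar"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(rec$qname)
  if (n == 0)
    return(data.frame(read_id = character(), mate = integer(),
                      contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), full_length = logical(),
                      stringsAsFactors = FALSE))
  flag <- rec$flag
  mate <- ifelse(bitwAnd(flag, 0x80) > 0, 2L, 1L)
  ref_width <- cigar_reference_width(rec$cigar)
  nm <- rec$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, n)
  data.frame(
    read_id = rec$qname,
    mate = mate,
    contig_id = as.character(rec$rname),
    start = rec$pos,
    end = rec$pos + ref_width - 1L,
    strand = ifelse(bitwAnd(flag, 0x10) > 0, "-", "+"),
    mismatches = as.integer(nm),
    full_length = !grepl("[SH]", rec$cigar),
    stringsAsFactors = FALSE)
}

# Reference-consumed width of each CIGAR string (M/=/X/D/N ops).
cigar_reference_width <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  vapply(ops, function(o) {
    len <- as.integer(sub("[MIDNSHP=X]$", "", o))
    typ <- sub("^\\d+", "", o)
    sum(len[typ %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

# Convert a SAM text file (or pass through a BAM) to a sorted, indexed BAM
# in tempdir; returns the BAM path.
local_sam_as_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
}

#' Filter mappings on accuracy
#'
#' Keeps only the most accurate hits: full-length alignments with at most
#' `max_mismatches` mismatches. This reproduces both the upstream
#' best-hit selection applied to aligner output and the stand-alone
#' sub-sampling utility used to shrink a mapping table before scaffolding.
#'
#' @param mappings Mapping data.frame from [read_mapping_table()].
#' @param max_mismatches Maximal mismatch count retained (default 3); `Inf`
#'   disables the mismatch filter.
#' @param require_full_length Drop clipped alignments (default TRUE).
#' @return The retained rows, original order preserved.
#' @export
filter_mappings <- function(mappings, max_mismatches = 3,
                            require_full_length = TRUE) {
  keep <- rep(TRUE, nrow(mappings))
  if (is.finite(max_mismatches)) {
    if (anyNA(mappings$mismatches))
      stop("mismatch counts are absent for some mappings (no NM tag); ",
           "set max_mismatches = Inf to disable the mismatch filter")
    keep <- keep & mappings$mismatches <= max_mismatches
  }
  if (require_full_length) keep <- keep & mappings$full_length
  mappings[keep, , drop = FALSE]
}

#' Write mappings in the 7-column tabulated dialect
#'
#' @param mappings Mapping data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mappings_tab7 <- function(mappings, path) {
  utils::write.table(
    mappings[, c("read_id", "mate", "contig_id", "start", "end", "strand",
                 "mismatches")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
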