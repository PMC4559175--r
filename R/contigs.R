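#' Read the contig info table
#'
#' Parses the delimited text table describing the input contigs: identifier,
#' mean fold-coverage and length, at the column positions declared in
#' `cfg$info_columns`. When `cfg$min_contig_coverage` is set, contigs below
#' that coverage are dropped (the usual way to discard contaminant contigs
#' in a non-axenic sequencing project).
#'
#' @param path Path to a whitespace- or tab-delimited text file.
#' @param cfg An [sm_config()] object (column indexes, coverage filter).
#' @return A data.frame with columns `contig_id`, `length`, `coverage`,
#'   one row per retained contig.
#' @export
read_contig_info <- function(path, cfg = sm_config()) {
  raw <- read_table_lines(path)
  if (raw$nrow == 0) {
    warning("contig info table is empty: ", path)
    return(data.frame(contig_id = character(), length = integer(),
                      coverage = numeric(), stringsAsFactors = FALSE))
  }
  ic <- cfg$info_columns
  need <- max(ic)
  short <- which(raw$n_fields < need)
  if (length(short))
    stop("contig info table ", path, ": line ", raw$lineno[short[1]],
         " has ", raw$n_fields[short[1]], " fields, need at least ", need)
  fields <- raw$fields
  contig_id <- vapply(fields, `[`, character(1), ic[["id"]])
  length_ <- suppressWarnings(
    as.numeric(vapply(fields, `[`, character(1), ic[["length"]])))
  coverage <- suppressWarnings(
    as.numeric(vapply(fields, `[`, character(1), ic[["coverage"]])))
  if (anyNA(length_))
    stop("non-numeric contig length at line ", which(is.na(length_))[1])
  if (anyNA(coverage))
    stop("non-numeric contig coverage at line ", which(is.na(coverage))[1])
  if (anyDuplicated(contig_id))
    stop("duplicate contig id(s): ",
         paste(unique(contig_id[duplicated(contig_id)]), collapse = ", "))
  if (any(length_ < 1)) stop("contig length must be >= 1")
  if (any(coverage < 0)) stop("contig coverage must be >= 0")
  df <- data.frame(contig_id = contig_id, length = as.integer(length_),
                   coverage = coverage, stringsAsFactors = FALSE)
  if (!is.na(cfg$min_contig_coverage))
    df <- df[df$coverage >= cfg$min_contig_coverage, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Tokenize a line-oriented table, skipping blank lines, tolerant of CRLF.
read_table_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  fields <- strsplit(lines, "[\t ]+")
  list(fields = fields,
       n_fields = vapply(fields, length, integer(1)),
       lineno = which(keep),
       nrow = length(lines))
}

#' Classify contigs as big or small
#'
#' A contig is "big" when its length is at least `cfg$big_contig_min`,
#' usually set to the upper bound of the main insert-size population: such a
#' contig is longer than any mate-pair span, so its two flanking neighbours
#' are the only contigs it can be cleanly linked to.
#'
#' @param contigs Contig info data.frame from [read_contig_info()].
#' @param cfg An [sm_config()] object with `big_contig_min` set.
#' @return `contigs` with an added logical column `big`.
#' @export
classify_contigs <- function(contigs, cfg) {
  if (is.na(cfg$big_contig_min))
    stop("big_contig_min is not set; set it (usually to main_insert_upper)")
  contigs$big <- contigs$length >= cfg$big_contig_min
  contigs
}

#' Estimate contig copy numbers from coverage ratios
#'
#' A collapsed repeat is assembled into a single consensus contig whose
#' coverage is a multiple of the single-copy coverage. Taking the largest
#' contig as the single-copy reference, the copy number of contig c is the
#' half-up-rounded ratio coverage(c) / coverage(largest contig), floored at
#' 1. The largest contig itself gets 1.
#'
#' @param contigs Contig info data.frame (`contig_id`, `length`, `coverage`).
#' @return A data.frame `contig_id`, `copies`.
#' @export
estimate_copy_numbers <- function(contigs) {
  if (nrow(contigs) == 0)
    return(data.frame(contig_id = character(), copies = integer(),
                      stringsAsFactors = FALSE))
  ref <- which.max(contigs$length)
  ref_cov <- contigs$coverage[ref]
  if (ref_cov <= 0)
    stop("largest contig (", contigs$contig_id[ref],
         ") has zero coverage; cannot normalize copy numbers")
  copies <- pmax(1L, as.integer(floor(contigs$coverage / ref_cov + 0.5)))
  copies[ref] <- 1L
  data.frame(contig_id = contigs$contig_id, copies = copies,
             stringsAsFactors = FALSE)
}

#' Write / read the contig copy number file
#'
#' A 2-column tab-separated table (`contig_id`, `copies`) intended for hand
#' correction before the scaffold step. On read, unknown trailing columns
#' are ignored and invariants (copies >= 1) are enforced.
#'
#' @param copy_numbers Data.frame `contig_id`, `copies`.
#' @param path File path.
#' @return `write_copy_numbers`: `path` invisibly; `read_copy_numbers`: the
#'   validated data.frame.
#' @export
write_copy_numbers <- function(copy_numbers, path) {
  stopifnot(all(c("contig_id", "copies") %in% names(copy_numbers)))
  utils::write.table(
    copy_numbers[, c("contig_id", "copies")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_copy_numbers
#' @export
read_copy_numbers <- function(path) {
  raw <- read_table_lines(path)
  if (raw$nrow == 0)
    return(data.frame(contig_id = character(), copies = integer(),
                      stringsAsFactors = FALSE))
  fields <- raw$fields
  # tolerate a header line
  if (identical(fields[[1]][1], "contig_id")) {
    fields <- fields[-1]
    raw$lineno <- raw$lineno[-1]
  }
  short <- which(vapply(fields, length, integer(1)) < 2)
  if (length(short))
    stop("copy number file ", path, ": line ", raw$lineno[short[1]],
         " has fewer than 2 columns")
  df <- data.frame(
    contig_id = vapply(fields, `[`, character(1), 1),
    copies = suppressWarnings(
      as.integer(vapply(fields, `[`, character(1), 2))),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$copies) | df$copies < 1)
  if (length(bad))
    stop("copy number file ", path, ": copies must be integers >= 1",
         " (offending line(s): ", paste(raw$lineno[bad], collapse = ", "),
         ")")
  if (anyDuplicated(df$contig_id))
    stop("copy number file ", path, ": duplicate contig id(s)")
  df
}
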