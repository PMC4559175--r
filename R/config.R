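#' Default pipeline configuration
#'
#' Builds the configuration object used by every stage of the scaffolding
#' pipeline. All values can be overridden by name, edited in the key=value
#' configuration file written by [write_config()], or set per run.
#'
#' The two insert-size bounds default to `NA`: they must be set by the user,
#' typically after inspecting the intra-contig insert-size histogram emitted
#' by [preprocess()]. `small_insert_upper = 0` declares that the library has
#' no short-insert contaminant population.
#'
#' @param small_insert_upper Upper bound (bp) of the short-insert
#'   contaminant population; pairs with a computable insert at or below this
#'   value are treated as noise. 0 means "no small-insert population".
#' @param main_insert_upper Upper bound (bp) of the main mate-pair insert
#'   population. Links implying an insert above `noisy_factor` times this
#'   value are discarded as noise, and a mate can only witness adjacency
#'   when it lies within this distance of a contig end.
#' @param histogram_bin Bin width (bp) for position histograms, default 50.
#' @param big_contig_min Minimal length (bp) of a "big" contig. Defaults to
#'   `main_insert_upper`: a contig longer than the insert size has an
#'   unambiguous neighbourhood.
#' @param min_contig_coverage Optional fold-coverage floor applied when the
#'   contig info table is read (used to drop contaminant contigs); `NA`
#'   disables the filter.
#' @param noisy_factor Multiplier on `main_insert_upper` above which an
#'   implied insert is considered noise (default 1.5).
#' @param min_link_support Minimal number of clean links required before a
#'   partner contig counts as a supported neighbour (default 5).
#' @param orientation_margin Minimal majority margin (in links) required to
#'   call the orientation of a candidate contig during extension (default 2).
#' @param multimap_cap When one read pair retains several best mappings, the
#'   pair is expanded into at most this many contig-pair combinations;
#'   beyond the cap the pair is dropped with a warning (default 4).
#' @param min_depth Minimal pileup depth below which a position is flagged
#'   as ambiguous, never corrected, by [correct_polymorphisms()] (default 5).
#' @param gap_size Number of N characters inserted between consecutive
#'   placements by [emit_scaffolds()] (default 50).
#' @param max_mismatches Mapping-accuracy filter: mappings with more
#'   mismatches are dropped (default 3).
#' @param require_full_length Keep only full-length (unclipped) alignments
#'   (default TRUE).
#' @param info_columns Integer positions of the id, coverage and length
#'   columns in the contig info table.
#' @param map_columns Integer positions of the read id, mate index, contig
#'   id, start, end, strand and mismatch columns in the 7-column mapping
#'   table.
#' @param output_names Named character vector mapping output roles to file
#'   names, used by the pipeline wrappers.
#' @param rng_seed Seed used by the dataset simulator.
#'
#' @return A list of class `sm_config`.
#' @export
#' @examples
#' cfg <- sm_config(small_insert_upper = 600, main_insert_upper = 4000)
#' cfg$big_contig_min
sm_config <- function(small_insert_upper = NA_real_,
                      main_insert_upper = NA_real_,
                      histogram_bin = 50,
                      big_contig_min = NA_real_,
                      min_contig_coverage = NA_real_,
                      noisy_factor = 1.5,
                      min_link_support = 5,
                      orientation_margin = 2,
                      multimap_cap = 4,
                      min_depth = 5,
                      gap_size = 50,
                      max_mismatches = 3,
                      require_full_length = TRUE,
                      info_columns = c(id = 1, coverage = 2, length = 3),
                      map_columns = c(read_id = 1, mate = 2, contig_id = 3,
                                      start = 4, end = 5, strand = 6,
                                      mismatches = 7),
                      output_names = c(
                        config = "scafmate_config.txt",
                        chimera = "chimera_resolution.tsv",
                        copy_number = "contig_copy_number.tsv",
                        scaffold_map = "scaffold_maps.tsv",
                        scaffolds_fasta = "scaffolds.fasta",
                        unscaffolded_fasta = "unscaffolded_contigs.fasta",
                        insert_histogram = "insert_size_histogram.tsv",
                        global_link_map = "global_link_map.tsv",
                        clean_global_link_map = "global_link_map_clean.tsv",
                        neighborhood_link_map = "neighborhood_link_map.tsv",
                        clean_neighborhood_link_map = "neighborhood_link_map_clean.tsv",
                        linkage_location = "linkage_location.tsv"),
                      rng_seed = 1L) {
  if (is.na(big_contig_min)) big_contig_min <- main_insert_upper
  cfg <- list(
    small_insert_upper = as.numeric(small_insert_upper),
    main_insert_upper = as.numeric(main_insert_upper),
    histogram_bin = as.numeric(histogram_bin),
    big_contig_min = as.numeric(big_contig_min),
    min_contig_coverage = as.numeric(min_contig_coverage),
    noisy_factor = as.numeric(noisy_factor),
    min_link_support = as.integer(min_link_support),
    orientation_margin = as.integer(orientation_margin),
    multimap_cap = as.integer(multimap_cap),
    min_depth = as.integer(min_depth),
    gap_size = as.integer(gap_size),
    max_mismatches = as.numeric(max_mismatches),
    require_full_length = isTRUE(require_full_length),
    info_columns = info_columns,
    map_columns = map_columns,
    output_names = output_names,
    rng_seed = as.integer(rng_seed))
  class(cfg) <- "sm_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sm_config"))
  if (!is.na(cfg$small_insert_upper) && cfg$small_insert_upper < 0)
    stop("small_insert_upper must be >= 0")
  if (!is.na(cfg$small_insert_upper) && !is.na(cfg$main_insert_upper) &&
      cfg$small_insert_upper >= cfg$main_insert_upper)
    stop("small_insert_upper must be smaller than main_insert_upper")
  if (!is.na(cfg$big_contig_min) && cfg$big_contig_min < 0)
    stop("big_contig_min must be >= 0")
  if (cfg$noisy_factor < 1)
    stop("noisy_factor must be >= 1")
  if (cfg$histogram_bin < 1)
    stop("histogram_bin must be >= 1")
  need <- c("id", "coverage", "length")
  if (!all(need %in% names(cfg$info_columns)))
    stop("info_columns must name ", paste(need, collapse = ", "))
  needm <- c("read_id", "mate", "contig_id", "start", "end", "strand",
             "mismatches")
  if (!all(needm %in% names(cfg$map_columns)))
    stop("map_columns must name ", paste(needm, collapse = ", "))
  invisible(cfg)
}

#' @export
print.sm_config <- function(x, ...) {
  cat("scafmate pipeline configuration\n")
  cat(sprintf("  insert bounds: small <= %s bp, main <= %s bp (noise > %.2g x main)\n",
              format(x$small_insert_upper), format(x$main_insert_upper),
              x$noisy_factor))
  cat(sprintf("  big contig min length: %s bp\n", format(x$big_contig_min)))
  cat(sprintf("  link support >= %d, orientation margin >= %d\n",
              x$min_link_support, x$orientation_margin))
  cat(sprintf("  mapping filter: <= %s mismatches, full length = %s\n",
              format(x$max_mismatches), x$require_full_length))
  invisible(x)
}

# scalar fields serialized in the flat config file, in file order
.config_scalar_fields <- c(
  "small_insert_upper", "main_insert_upper", "histogram_bin",
  "big_contig_min", "min_contig_coverage", "noisy_factor",
  "min_link_support", "orientation_margin", "multimap_cap", "min_depth",
  "gap_size", "max_mismatches", "require_full_length", "rng_seed")

#' Write the configuration to a hand-editable key=value file
#'
#' The file is flat text: `key = value` lines with `#` comments. Vector
#' fields (column indexes, output names) are written as `group.key = value`.
#'
#' @param cfg An `sm_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  fmt_val <- function(v) {
    if (is.logical(v)) return(ifelse(v, "true", "false"))
    if (is.na(v)) return("NA")
    format(v, scientific = FALSE, trim = TRUE)
  }
  lines <- c(
    "# scafmate pipeline configuration",
    "# insert-size bounds (bp); read them off the insert-size histogram",
    "# emitted by preprocess. small_insert_upper = 0 means the library has",
    "# no short-insert population; NA means 'not yet determined'.",
    vapply(.config_scalar_fields,
           function(k) sprintf("%s = %s", k, fmt_val(cfg[[k]])),
           character(1)),
    "# 1-based column indexes in the contig info table",
    sprintf("info_columns.%s = %d", names(cfg$info_columns),
            as.integer(cfg$info_columns)),
    "# 1-based column indexes in the 7-column mapping table",
    sprintf("map_columns.%s = %d", names(cfg$map_columns),
            as.integer(cfg$map_columns)),
    "# default output file names",
    sprintf("output_names.%s = %s", names(cfg$output_names),
            cfg$output_names))
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration file written by [write_config()]
#'
#' Unknown keys are ignored with a warning so hand-edited files with extra
#' annotations still load.
#'
#' @param path Path to a key=value configuration file.
#' @return An `sm_config` object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad))
    stop("malformed configuration line(s): ",
         paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  cfg <- sm_config(main_insert_upper = NA)  # template with defaults
  parse_scalar <- function(v) {
    if (v %in% c("true", "TRUE")) return(TRUE)
    if (v %in% c("false", "FALSE")) return(FALSE)
    if (v == "NA") return(NA_real_)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k %in% .config_scalar_fields) {
      cfg[[k]] <- parse_scalar(vals[i])
    } else if (startsWith(k, "info_columns.")) {
      cfg$info_columns[[sub("^info_columns\\.", "", k)]] <-
        as.integer(vals[i])
    } else if (startsWith(k, "map_columns.")) {
      cfg$map_columns[[sub("^map_columns\\.", "", k)]] <- as.integer(vals[i])
    } else if (startsWith(k, "output_names.")) {
      cfg$output_names[[sub("^output_names\\.", "", k)]] <- vals[i]
    } else {
      warning("ignoring unknown configuration key: ", k)
    }
  }
  cfg$min_link_support <- as.integer(cfg$min_link_support)
  cfg$orientation_margin <- as.integer(cfg$orientation_margin)
  cfg$multimap_cap <- as.integer(cfg$multimap_cap)
  cfg$min_depth <- as.integer(cfg$min_depth)
  cfg$gap_size <- as.integer(cfg$gap_size)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  cfg$require_full_length <- isTRUE(cfg$require_full_length)
  validate_config(cfg)
  cfg
}
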