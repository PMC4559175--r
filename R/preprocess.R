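#' Preprocess: insert model, links, chimera detection, copy numbers
#'
#' Runs the whole preprocessing stage on in-memory inputs: filters the
#' mappings on accuracy, estimates the insert-size model, builds raw and
#' clean links, detects chimera candidates and estimates copy numbers.
#' When `out_dir` is given, the two editable verdict files (chimera
#' resolution, contig copy number) are written there; with
#' `dumpfiles = TRUE` the diagnostic dumpfiles are written too:
#' the insert-size histogram, raw and clean global link maps, raw and
#' clean neighborhood link maps, and the per-contig linkage-location
#' table.
#'
#' If the insert-size bounds are not set in `cfg`, the histogram is still
#' written (when `out_dir` is given) and the run stops with instructions:
#' the bounds are read off the histogram by the user, entered in the
#' configuration, and preprocess is re-run — the semi-automatic loop this
#' pipeline is built around.
#'
#' @param contigs Contig info data.frame from [read_contig_info()].
#' @param mappings Mapping data.frame from [read_mapping_table()].
#' @param cfg An [sm_config()] object.
#' @param out_dir Optional output directory.
#' @param dumpfiles Write the diagnostic dumpfiles (default FALSE).
#' @return A list: `model`, `links` (raw/clean), `copy_numbers`,
#'   `chimera_records`, `filtered_mappings`.
#' @export
preprocess <- function(contigs, mappings, cfg, out_dir = NULL,
                       dumpfiles = FALSE) {
  mappings <- filter_mappings(mappings, cfg$max_mismatches,
                              cfg$require_full_length)
  model <- estimate_insert_model(mappings, cfg)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.na(cfg$small_insert_upper) || is.na(cfg$main_insert_upper)) {
    if (!is.null(out_dir)) {
      hp <- file.path(out_dir, cfg$output_names[["insert_histogram"]])
      write_insert_histogram(model, hp)
      stop("insert-size bounds are not set. Inspect the histogram ",
           "written to ", hp, ", choose small_insert_upper and ",
           "main_insert_upper, update the configuration and re-run.",
           call. = FALSE)
    }
    stop("insert-size bounds are not set; inspect the insert-size ",
         "histogram (estimate_insert_model) and set small_insert_upper ",
         "and main_insert_upper in the configuration.", call. = FALSE)
  }
  links <- build_links(mappings, contigs, cfg)
  copy_numbers <- estimate_copy_numbers(contigs)
  chimera_records <- detect_chimerae(links$raw, contigs, copy_numbers,
                                     cfg)
  message(sprintf(
    "preprocess: %d mappings kept, %d raw / %d clean links, %d contig(s) flagged as chimera candidates",
    nrow(mappings), nrow(links$raw), nrow(links$clean),
    sum(chimera_records$flagged)))
  if (!is.null(out_dir)) {
    on <- cfg$output_names
    write_chimera_file(chimera_records, file.path(out_dir, on[["chimera"]]))
    write_copy_numbers(copy_numbers, file.path(out_dir, on[["copy_number"]]))
    if (dumpfiles) {
      write_insert_histogram(model,
                             file.path(out_dir, on[["insert_histogram"]]))
      write_link_map(global_link_map(links$raw, contigs),
                     file.path(out_dir, on[["global_link_map"]]))
      write_link_map(global_link_map(links$clean, contigs),
                     file.path(out_dir, on[["clean_global_link_map"]]))
      write_neighborhood_map(neighborhood_link_map(links$raw),
                             file.path(out_dir, on[["neighborhood_link_map"]]))
      write_neighborhood_map(neighborhood_link_map(links$clean),
                             file.path(out_dir,
                                       on[["clean_neighborhood_link_map"]]))
      ll <- do.call(rbind, lapply(contigs$contig_id, function(cid) {
        h <- linkage_location_histogram(cid, links$raw, contigs,
                                        bin = cfg$histogram_bin)
        h$contig_id <- cid
        h[, c("contig_id", "bin_start", "partner", "count")]
      }))
      utils::write.table(ll, file.path(out_dir, on[["linkage_location"]]),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(model = model, links = links, copy_numbers = copy_numbers,
       chimera_records = chimera_records, filtered_mappings = mappings)
}

#' Write the insert-size histogram dumpfile
#'
#' @param model An `sm_insert_model`.
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_insert_histogram <- function(model, path) {
  utils::write.table(model$histogram, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a global link map matrix as TSV
#'
#' @param m Matrix from [global_link_map()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_link_map <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Write a neighborhood link map as TSV
#'
#' @param nm Data.frame from [neighborhood_link_map()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_neighborhood_map <- function(nm, path) {
  utils::write.table(nm, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
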