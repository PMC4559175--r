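#' Detect chimera candidates from clean link neighbourhoods
#'
#' A single-copy contig longer than the insert size can have at most two
#' big neighbours in the chromosome — one off each end. A chimera joining
#' two distant loci inherits the neighbourhoods of both, so it shows
#' supported links to more big partners than geometry allows. For every
#' single-copy big contig the detector counts, at each end, the distinct
#' big partners supported by at least `cfg$min_link_support` inter-contig
#' links; a contig is flagged when one end has two or more such partners or
#' the contig totals three or more across both ends.
#'
#' Detection runs on the raw link set: the extra partners of a chimera
#' attach at its internal breakpoint, far from both contig ends, so links
#' to them are exactly the ones the clean-link distance rules discard as
#' unusable for scaffolding. Ends are labelled by the nearer contig end;
#' stray mismapped pairs stay below `min_link_support`.
#'
#' Detection is advisory: every contig is listed, flagged or not, as a
#' single unsplit component spanning its whole length. Splitting is a
#' manual edit of the resulting chimera resolution file, guided by
#' [linkage_location_histogram()].
#'
#' Multi-copy contigs legitimately occur at several genomic locations and
#' are exempt from the two-neighbour expectation.
#'
#' @param links A link data.frame from [build_links()] (use the raw set).
#' @param contigs Contig info data.frame.
#' @param copy_numbers Data.frame `contig_id`, `copies` (from
#'   [estimate_copy_numbers()] or a hand-edited file).
#' @param cfg An [sm_config()] object.
#' @return A chimera record data.frame: `contig_id`, `component_id`,
#'   `component_start`, `component_end`, `flagged`.
#' @export
detect_chimerae <- function(links, contigs, copy_numbers, cfg) {
  contigs <- classify_contigs(contigs, cfg)
  copies <- stats::setNames(copy_numbers$copies, copy_numbers$contig_id)
  big_ids <- contigs$contig_id[contigs$big]
  single <- contigs$contig_id[
    ifelse(is.na(copies[contigs$contig_id]), 1L,
           copies[contigs$contig_id]) == 1L]
  support <- end_partner_support(links)
  flagged <- vapply(contigs$contig_id, function(cid) {
    if (!(cid %in% big_ids) || !(cid %in% single)) return(FALSE)
    s <- support[support$contig == cid &
                   support$partner %in% big_ids &
                   support$count >= cfg$min_link_support, , drop = FALSE]
    if (nrow(s) == 0) return(FALSE)
    per_end <- tapply(s$partner, s$end, function(p) length(unique(p)))
    total <- length(unique(s$partner))
    any(per_end >= 2) || total >= 3
  }, logical(1))
  data.frame(contig_id = contigs$contig_id,
             component_id = contigs$contig_id,
             component_start = 1L,
             component_end = contigs$length,
             flagged = unname(flagged),
             stringsAsFactors = FALSE)
}

# Clean-link support aggregated per (contig, end, partner), both roles.
end_partner_support <- function(links) {
  usable <- links[!links$intra & !is.na(links$end_a) & !is.na(links$end_b),
                  , drop = FALSE]
  both <- rbind(
    data.frame(contig = usable$contig_a, end = usable$end_a,
               partner = usable$contig_b, partner_end = usable$end_b,
               stringsAsFactors = FALSE),
    data.frame(contig = usable$contig_b, end = usable$end_b,
               partner = usable$contig_a, partner_end = usable$end_a,
               stringsAsFactors = FALSE))
  if (nrow(both) == 0) {
    both$count <- integer()
    return(both)
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(both))),
                          both, FUN = length)
  rownames(agg) <- NULL
  agg
}

#' Write / read the chimera resolution file
#'
#' A 5-column tab-separated table (`contig_id`, `component_id`,
#' `component_start`, `component_end`, `flagged`) meant to be hand-edited:
#' splitting a chimeric contig means replacing its single line by one line
#' per component, with intervals that tile the contig (overlaps allowed, no
#' gaps). On re-import the tiling invariants are validated and offending
#' lines reported.
#'
#' @param records Chimera record data.frame.
#' @param path File path.
#' @return `write_chimera_file`: `path` invisibly; `read_chimera_file`: the
#'   validated record data.frame.
#' @export
write_chimera_file <- function(records, path) {
  stopifnot(all(c("contig_id", "component_id", "component_start",
                  "component_end", "flagged") %in% names(records)))
  out <- records[, c("contig_id", "component_id", "component_start",
                     "component_end", "flagged")]
  out$flagged <- as.integer(out$flagged)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_chimera_file
#' @export
read_chimera_file <- function(path) {
  raw <- read_table_lines(path)
  if (raw$nrow == 0)
    return(data.frame(contig_id = character(), component_id = character(),
                      component_start = integer(),
                      component_end = integer(), flagged = logical(),
                      stringsAsFactors = FALSE))
  fields <- raw$fields
  if (identical(fields[[1]][1], "contig_id")) {
    fields <- fields[-1]
    raw$lineno <- raw$lineno[-1]
  }
  short <- which(vapply(fields, length, integer(1)) < 5)
  if (length(short))
    stop("chimera file ", path, ": line ", raw$lineno[short[1]],
         " has fewer than 5 columns")
  df <- data.frame(
    contig_id = vapply(fields, `[`, character(1), 1),
    component_id = vapply(fields, `[`, character(1), 2),
    component_start = suppressWarnings(
      as.integer(vapply(fields, `[`, character(1), 3))),
    component_end = suppressWarnings(
      as.integer(vapply(fields, `[`, character(1), 4))),
    flagged = vapply(fields, `[`, character(1), 5) %in%
      c("1", "TRUE", "true"),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$component_start) | is.na(df$component_end) |
                 df$component_start < 1 |
                 df$component_end < df$component_start)
  if (length(bad))
    stop("chimera file ", path, ": invalid component interval(s) at ",
         "line(s) ", paste(raw$lineno[bad], collapse = ", "))
  validate_chimera_records(df, lineno = raw$lineno, source = path)
  df
}

# Components of each contig must be sorted by start, begin at 1, and tile
# the contig without gaps (overlaps are allowed). End-vs-contig-length is
# checked where contig lengths are available.
validate_chimera_records <- function(records, contigs = NULL,
                                     lineno = seq_len(nrow(records)),
                                     source = "chimera records") {
  if (anyDuplicated(records$component_id))
    stop(source, ": duplicate component id(s)")
  for (cid in unique(records$contig_id)) {
    idx <- which(records$contig_id == cid)
    comp <- records[idx, , drop = FALSE]
    if (is.unsorted(comp$component_start))
      stop(source, ": components of ", cid, " are not sorted by start ",
           "(lines ", paste(lineno[idx], collapse = ", "), ")")
    if (comp$component_start[1] != 1)
      stop(source, ": first component of ", cid, " must start at 1")
    if (nrow(comp) > 1) {
      gaps <- comp$component_start[-1] > comp$component_end[-nrow(comp)] + 1
      if (any(gaps))
        stop(source, ": components of ", cid, " leave uncovered gaps ",
             "(line ", lineno[idx][which(gaps)[1] + 1], ")")
    }
    if (!is.null(contigs)) {
      clen <- contigs$length[match(cid, contigs$contig_id)]
      if (is.na(clen))
        stop(source, ": unknown contig ", cid)
      if (comp$component_end[nrow(comp)] != clen)
        stop(source, ": components of ", cid, " must end at the contig ",
             "length (", clen, ")")
    }
  }
  invisible(records)
}

#' Apply chimera resolution: split contigs and redistribute mappings
#'
#' Replaces each split contig by its components (lengths from the component
#' intervals, coverage inherited) and reassigns every mate mapping of a
#' split contig to a component, rebasing its coordinates. A mapping whose
#' midpoint falls inside exactly one component goes there; in an overlap
#' region it goes to the component in which it lies farther from the shared
#' boundary. Links are then rebuilt from the revised mappings with
#' [build_links()].
#'
#' @param contigs Contig info data.frame.
#' @param mappings Mapping data.frame.
#' @param records Chimera record data.frame (validated).
#' @return A list `contigs`, `mappings` with components in place of split
#'   contigs.
#' @export
apply_chimera_resolution <- function(contigs, mappings, records) {
  validate_chimera_records(records, contigs = contigs)
  split_ids <- unique(records$contig_id[duplicated(records$contig_id)])
  renamed <- records$contig_id[records$component_id != records$contig_id &
                                 !(records$contig_id %in% split_ids)]
  affected <- union(split_ids, renamed)
  if (length(affected) == 0)
    return(list(contigs = contigs, mappings = mappings))

  keep <- !(contigs$contig_id %in% affected)
  rec <- records[records$contig_id %in% affected, , drop = FALSE]
  comp_contigs <- data.frame(
    contig_id = rec$component_id,
    length = rec$component_end - rec$component_start + 1L,
    coverage = contigs$coverage[match(rec$contig_id, contigs$contig_id)],
    stringsAsFactors = FALSE)
  new_contigs <- rbind(contigs[keep, c("contig_id", "length", "coverage")],
                       comp_contigs)
  rownames(new_contigs) <- NULL

  move <- mappings$contig_id %in% affected
  kept_maps <- mappings[!move, , drop = FALSE]
  mv <- mappings[move, , drop = FALSE]
  if (nrow(mv)) {
    mv_new <- do.call(rbind, lapply(seq_len(nrow(mv)), function(i) {
      comp <- rec[rec$contig_id == mv$contig_id[i], , drop = FALSE]
      pos <- (mv$start[i] + mv$end[i]) %/% 2
      inside <- which(comp$component_start <= pos &
                        pos <= comp$component_end)
      if (length(inside) == 0)
        stop("mapping at ", mv$contig_id[i], ":", pos,
             " falls outside every component — invalid chimera tiling")
      if (length(inside) > 1) {
        # distance from the position to the boundary each component shares
        # with the overlap: farther in wins
        margin <- vapply(inside, function(k) {
          left <- if (k > 1 &&
                      comp$component_start[k] <= pos) {
            pos - comp$component_start[k]
          } else Inf
          right <- if (k < nrow(comp) &&
                       comp$component_end[k] >= pos) {
            comp$component_end[k] - pos
          } else Inf
          min(left, right)
        }, numeric(1))
        inside <- inside[which.max(margin)]
      }
      k <- inside[1]
      row <- mv[i, , drop = FALSE]
      row$contig_id <- comp$component_id[k]
      comp_len <- comp$component_end[k] - comp$component_start[k] + 1L
      row$start <- max(1L, mv$start[i] - comp$component_start[k] + 1L)
      row$end <- min(comp_len, mv$end[i] - comp$component_start[k] + 1L)
      row
    }))
    kept_maps <- rbind(kept_maps, mv_new)
  }
  rownames(kept_maps) <- NULL
  list(contigs = new_contigs, mappings = kept_maps)
}
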