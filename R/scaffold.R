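#' @title Scaffold map object
#' @description A scaffold map is the central editable artifact of the
#'   pipeline: the ordered, oriented, copy-annotated placements of contigs
#'   into scaffolds, plus the residual set of unscaffolded contigs.
#'   Placements carry a provenance tag: `ISE` for the iterative scaffold
#'   extender, `SCI` for the small-contig inserter.
#' @param placements Data.frame `scaffold_id`, `rank`, `contig_id`,
#'   `orientation` (`+`/`-`), `copies_placed`, `provenance`.
#' @param unscaffolded Character vector of contig ids left unplaced.
#' @return An object of class `sm_scaffold_map`.
#' @export
scaffold_map <- function(placements, unscaffolded = character()) {
  stopifnot(all(c("scaffold_id", "rank", "contig_id", "orientation",
                  "copies_placed", "provenance") %in% names(placements)))
  for (sid in unique(placements$scaffold_id)) {
    r <- placements$rank[placements$scaffold_id == sid]
    if (!identical(sort(r), seq_along(r)))
      stop("ranks of scaffold ", sid, " are not consecutive from 1")
  }
  if (any(placements$copies_placed < 1))
    stop("copies_placed must be >= 1")
  structure(list(placements = placements,
                 unscaffolded = as.character(unscaffolded)),
            class = "sm_scaffold_map")
}

#' @export
print.sm_scaffold_map <- function(x, ...) {
  ns <- length(unique(x$placements$scaffold_id))
  cat(sprintf("scaffold map: %d scaffold(s), %d placement(s), %d unscaffolded contig(s)\n",
              ns, nrow(x$placements), length(x$unscaffolded)))
  invisible(x)
}

# Which end of a placement faces out of the scaffold on each side.
# A '+' placement keeps its 5' end on the left (lower-rank) side.
facing_end <- function(orientation, side = c("left", "right")) {
  side <- match.arg(side)
  if (side == "left") ifelse(orientation == "+", "5'", "3'")
  else ifelse(orientation == "+", "3'", "5'")
}

#' Iterative scaffold extender (ISE)
#'
#' Greedy ordering and orientation of contigs from clean link support.
#' The largest unplaced big contig seeds a scaffold; the scaffold is then
#' grown at both ends. At a growing end, candidates are the unplaced
#' single-copy contigs linked to the terminal placement's outward end by at
#' least `cfg$min_link_support` clean links; big contigs take priority over
#' small single-copy ones, and within a class the candidate with the most
#' supporting links wins (ties: longer contig, then lexicographic id). The
#' candidate's orientation is set so that the majority of supporting links
#' attach its nearer end to the scaffold; a majority margin below
#' `cfg$orientation_margin` links rejects the candidate at that step.
#' One side is extended to exhaustion, then the other, repeating until
#' neither advances; seeding repeats until every big contig is placed.
#'
#' Multi-copy contigs are excluded: they occur at several genomic
#' locations, so their link neighbourhoods are ambiguous (they are the
#' usual cause of scaffold termination). They are handled later by
#' [run_sci()].
#'
#' @param contigs Contig info data.frame.
#' @param clean_links Clean link data.frame from [build_links()].
#' @param copy_numbers Data.frame `contig_id`, `copies`.
#' @param cfg An [sm_config()] object.
#' @return An `sm_scaffold_map` with `ISE` placements.
#' @export
run_ise <- function(contigs, clean_links, copy_numbers, cfg) {
  contigs <- classify_contigs(contigs, cfg)
  copies <- stats::setNames(copy_numbers$copies, copy_numbers$contig_id)
  copies_of <- function(id) {
    v <- unname(copies[id]); ifelse(is.na(v), 1L, v)
  }
  eligible <- contigs$contig_id[copies_of(contigs$contig_id) == 1L]
  big <- contigs$contig_id[contigs$big]
  len <- stats::setNames(contigs$length, contigs$contig_id)
  support <- end_partner_support(clean_links)

  seed_pool <- intersect(big, eligible)
  degenerate <- length(seed_pool) == 0
  if (degenerate) {
    seed_pool <- eligible
    if (length(seed_pool))
      message("no big single-copy contig available; seeding from the ",
              "largest single-copy contig")
  }

  placed <- character()
  placements <- list()
  scaffold_n <- 0L

  pick_candidate <- function(terminal_id, outward_end, side) {
    s <- support[support$contig == terminal_id &
                   support$end == outward_end &
                   !(support$partner %in% placed) &
                   support$partner %in% eligible, , drop = FALSE]
    if (nrow(s) == 0) return(NULL)
    tot <- tapply(s$count, s$partner, sum)
    cands <- names(tot)[tot >= cfg$min_link_support]
    if (length(cands) == 0) return(NULL)
    ord <- order(!(cands %in% big),            # big contigs first
                 -as.numeric(tot[cands]),
                 -as.numeric(len[cands]),
                 cands)
    for (cand in cands[ord]) {
      n5 <- sum(s$count[s$partner == cand & s$partner_end == "5'"])
      n3 <- sum(s$count[s$partner == cand & s$partner_end == "3'"])
      if (abs(n5 - n3) < cfg$orientation_margin) {
        message("ISE: contradictory orientation evidence for ", cand,
                " (5':", n5, " vs 3':", n3, "); candidate rejected")
        next
      }
      inward <- if (n5 > n3) "5'" else "3'"
      orientation <- if (side == "right") {
        if (inward == "5'") "+" else "-"   # inward end faces left
      } else {
        if (inward == "3'") "+" else "-"   # inward end faces right
      }
      return(list(contig_id = cand, orientation = orientation))
    }
    NULL
  }

  while (length(setdiff(seed_pool, placed)) > 0) {
    pool <- setdiff(seed_pool, placed)
    seed <- pool[order(-as.numeric(len[pool]), pool)][1]
    chain <- data.frame(contig_id = seed, orientation = "+",
                        stringsAsFactors = FALSE)
    placed <- c(placed, seed)
    repeat {
      advanced <- FALSE
      repeat {  # grow the right side to exhaustion
        term <- chain[nrow(chain), ]
        cand <- pick_candidate(term$contig_id,
                               facing_end(term$orientation, "right"),
                               side = "right")
        if (is.null(cand)) break
        chain <- rbind(chain,
                       data.frame(contig_id = cand$contig_id,
                                  orientation = cand$orientation,
                                  stringsAsFactors = FALSE))
        placed <- c(placed, cand$contig_id)
        advanced <- TRUE
      }
      repeat {  # then the left side
        term <- chain[1, ]
        cand <- pick_candidate(term$contig_id,
                               facing_end(term$orientation, "left"),
                               side = "left")
        if (is.null(cand)) break
        chain <- rbind(data.frame(contig_id = cand$contig_id,
                                  orientation = cand$orientation,
                                  stringsAsFactors = FALSE),
                       chain)
        placed <- c(placed, cand$contig_id)
        advanced <- TRUE
      }
      if (!advanced) break
    }
    scaffold_n <- scaffold_n + 1L
    placements[[scaffold_n]] <- data.frame(
      scaffold_id = sprintf("scaffold_%d", scaffold_n),
      rank = seq_len(nrow(chain)),
      contig_id = chain$contig_id,
      orientation = chain$orientation,
      copies_placed = 1L,
      provenance = "ISE",
      stringsAsFactors = FALSE)
  }

  pl <- if (length(placements)) do.call(rbind, placements) else
    data.frame(scaffold_id = character(), rank = integer(),
               contig_id = character(), orientation = character(),
               copies_placed = integer(), provenance = character(),
               stringsAsFactors = FALSE)
  scaffold_map(pl, unscaffolded = setdiff(contigs$contig_id, placed))
}

#' Small-contig inserter (SCI)
#'
#' Attempts to insert the contigs left over after [run_ise()] — small
#' single-copy and all multi-copy contigs — into the existing scaffolds.
#' For each such contig every junction between consecutive placements is
#' scored by the clean links connecting the contig to the two inward-facing
#' placement ends; junctions reaching `cfg$min_link_support` total links
#' are congruent insertion points. The contig is inserted at the
#' best-supported congruent junctions, at most once per junction and at
#' most its copy number in total (`copies_placed` records the copy number).
#' Orientation follows the majority of end-to-end link evidence.
#'
#' No contig is ever added before the first or after the last placement of
#' a scaffold, so scaffold edges stay as ISE left them and scaffolds are
#' never merged.
#'
#' @param map An `sm_scaffold_map` from [run_ise()].
#' @param contigs Contig info data.frame.
#' @param clean_links Clean link data.frame.
#' @param copy_numbers Data.frame `contig_id`, `copies`.
#' @param cfg An [sm_config()] object.
#' @return The augmented `sm_scaffold_map`.
#' @export
run_sci <- function(map, contigs, clean_links, copy_numbers, cfg) {
  contigs <- classify_contigs(contigs, cfg)
  copies <- stats::setNames(copy_numbers$copies, copy_numbers$contig_id)
  copies_of <- function(id) {
    v <- unname(copies[id]); ifelse(is.na(v), 1L, v)
  }
  len <- stats::setNames(contigs$length, contigs$contig_id)
  support <- end_partner_support(clean_links)
  pl <- map$placements

  remaining <- intersect(map$unscaffolded,
                         contigs$contig_id[!contigs$big])
  remaining <- remaining[order(-as.numeric(len[remaining]), remaining)]
  if (length(remaining) == 0 || nrow(pl) == 0) return(map)

  sup_count <- function(from_id, from_end, to_id, to_end) {
    s <- support$count[support$contig == from_id &
                         support$end == from_end &
                         support$partner == to_id &
                         support$partner_end == to_end]
    if (length(s)) sum(s) else 0L
  }

  insertions <- list()
  placed_ids <- character()
  for (cid in remaining) {
    junctions <- list()
    for (sid in unique(pl$scaffold_id)) {
      sp <- pl[pl$scaffold_id == sid, , drop = FALSE]
      sp <- sp[order(sp$rank), , drop = FALSE]
      if (nrow(sp) < 2) next
      for (i in seq_len(nrow(sp) - 1)) {
        L <- sp[i, ]; R <- sp[i + 1, ]
        eL <- facing_end(L$orientation, "right")
        eR <- facing_end(R$orientation, "left")
        nL5 <- sup_count(L$contig_id, eL, cid, "5'")
        nL3 <- sup_count(L$contig_id, eL, cid, "3'")
        nR5 <- sup_count(R$contig_id, eR, cid, "5'")
        nR3 <- sup_count(R$contig_id, eR, cid, "3'")
        total <- nL5 + nL3 + nR5 + nR3
        if (total < cfg$min_link_support) next
        n_plus <- nL5 + nR3   # '+' keeps the 5' end toward L
        n_minus <- nL3 + nR5
        junctions[[length(junctions) + 1]] <- data.frame(
          scaffold_id = sid, after_rank = L$rank, total = total,
          orientation = if (n_plus >= n_minus) "+" else "-",
          stringsAsFactors = FALSE)
      }
    }
    if (length(junctions) == 0) next
    jt <- do.call(rbind, junctions)
    jt <- jt[order(-jt$total, jt$scaffold_id, jt$after_rank), , drop = FALSE]
    budget <- copies_of(cid)
    if (nrow(jt) > budget)
      message("SCI: ", cid, " has ", nrow(jt), " congruent insertion ",
              "points for a copy budget of ", budget,
              "; keeping the best-supported")
    take <- jt[seq_len(min(nrow(jt), budget)), , drop = FALSE]
    take$contig_id <- cid
    take$copies_placed <- budget
    insertions[[length(insertions) + 1]] <- take
    placed_ids <- c(placed_ids, cid)
  }
  if (length(insertions) == 0) return(map)
  ins <- do.call(rbind, insertions)

  # rebuild each scaffold, splicing insertions after their anchor ranks
  out <- list()
  for (sid in unique(pl$scaffold_id)) {
    sp <- pl[pl$scaffold_id == sid, , drop = FALSE]
    sp <- sp[order(sp$rank), , drop = FALSE]
    rows <- list()
    for (i in seq_len(nrow(sp))) {
      rows[[length(rows) + 1]] <- sp[i, c("contig_id", "orientation",
                                          "copies_placed", "provenance")]
      here <- ins[ins$scaffold_id == sid & ins$after_rank == sp$rank[i], ,
                  drop = FALSE]
      if (nrow(here)) {
        here <- here[order(-here$total, here$contig_id), , drop = FALSE]
        for (j in seq_len(nrow(here)))
          rows[[length(rows) + 1]] <- data.frame(
            contig_id = here$contig_id[j],
            orientation = here$orientation[j],
            copies_placed = here$copies_placed[j],
            provenance = "SCI", stringsAsFactors = FALSE)
      }
    }
    blk <- do.call(rbind, rows)
    blk$scaffold_id <- sid
    blk$rank <- seq_len(nrow(blk))
    out[[length(out) + 1]] <- blk[, c("scaffold_id", "rank", "contig_id",
                                      "orientation", "copies_placed",
                                      "provenance")]
  }
  scaffold_map(do.call(rbind, out),
               unscaffolded = setdiff(map$unscaffolded, placed_ids))
}

#' Full automatic scaffolding step
#'
#' Applies the (possibly hand-edited) chimera resolution, rebuilds clean
#' links on the revised contigs, then runs [run_ise()] and [run_sci()].
#' Afterwards, clean link support between the outward ends of scaffold
#' terminals is reported (via `message`) as an aid for manual
#' circularization and scaffold joining.
#'
#' @param contigs Contig info data.frame.
#' @param mappings Filtered mapping data.frame.
#' @param chimera_records Chimera record data.frame (possibly hand-edited).
#' @param copy_numbers Copy-number data.frame (possibly hand-edited).
#' @param cfg An [sm_config()] object with insert bounds set.
#' @return A list: `map` (`sm_scaffold_map`), `contigs` (revised),
#'   `links` (raw/clean list), `terminal_links` (data.frame of scaffold
#'   end-to-end support).
#' @export
scaffold_contigs <- function(contigs, mappings, chimera_records = NULL,
                             copy_numbers = NULL, cfg = sm_config()) {
  if (!is.null(chimera_records)) {
    res <- apply_chimera_resolution(contigs, mappings, chimera_records)
    contigs <- res$contigs
    mappings <- res$mappings
    if (!is.null(copy_numbers)) {
      # map copy numbers of split contigs onto their components
      idx <- match(chimera_records$contig_id, copy_numbers$contig_id)
      extra <- data.frame(contig_id = chimera_records$component_id,
                          copies = copy_numbers$copies[idx],
                          stringsAsFactors = FALSE)
      extra <- extra[!is.na(extra$copies) &
                       !(extra$contig_id %in% copy_numbers$contig_id), ,
                     drop = FALSE]
      copy_numbers <- rbind(copy_numbers, extra)
      copy_numbers <- copy_numbers[
        copy_numbers$contig_id %in% contigs$contig_id, , drop = FALSE]
    }
  }
  if (is.null(copy_numbers)) copy_numbers <- estimate_copy_numbers(contigs)
  links <- build_links(mappings, contigs, cfg)
  map <- run_ise(contigs, links$clean, copy_numbers, cfg)
  map <- run_sci(map, contigs, links$clean, copy_numbers, cfg)
  term <- terminal_link_report(map, links$clean, cfg)
  if (nrow(term))
    message("terminal-to-terminal link support (circularization aid):\n",
            paste(utils::capture.output(print(term)), collapse = "\n"))
  list(map = map, contigs = contigs, links = links, terminal_links = term)
}

# Clean-link support between outward ends of scaffold terminals, including
# a scaffold's own two ends (evidence for circularity).
terminal_link_report <- function(map, clean_links, cfg) {
  pl <- map$placements
  empty <- data.frame(scaffold_a = character(), scaffold_b = character(),
                      side_a = character(), side_b = character(),
                      count = integer(), stringsAsFactors = FALSE)
  if (nrow(pl) == 0) return(empty)
  support <- end_partner_support(clean_links)
  terms <- do.call(rbind, lapply(unique(pl$scaffold_id), function(sid) {
    sp <- pl[pl$scaffold_id == sid, , drop = FALSE]
    sp <- sp[order(sp$rank), , drop = FALSE]
    data.frame(scaffold_id = sid,
               side = c("left", "right"),
               contig_id = c(sp$contig_id[1], sp$contig_id[nrow(sp)]),
               end = c(facing_end(sp$orientation[1], "left"),
                       facing_end(sp$orientation[nrow(sp)], "right")),
               stringsAsFactors = FALSE)
  }))
  rows <- list()
  for (i in seq_len(nrow(terms))) for (j in seq_len(nrow(terms))) {
    if (j <= i) next
    n <- support$count[support$contig == terms$contig_id[i] &
                         support$end == terms$end[i] &
                         support$partner == terms$contig_id[j] &
                         support$partner_end == terms$end[j]]
    n <- if (length(n)) sum(n) else 0L
    if (n >= cfg$min_link_support)
      rows[[length(rows) + 1]] <- data.frame(
        scaffold_a = terms$scaffold_id[i], scaffold_b = terms$scaffold_id[j],
        side_a = terms$side[i], side_b = terms$side[j], count = n,
        stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else empty
}

#' Write / read the scaffold maps file
#'
#' Line-oriented, hand-editable text: a comment header, then one block per
#' scaffold with one placement per line (`scaffold_id`, `rank`,
#' `contig_id`, `orientation`, `copies_placed`, `provenance`, tab
#' separated), blocks separated by a blank line. Unscaffolded contigs are
#' listed at the end as `# unscaffolded: <id>` comment lines. Unknown
#' trailing columns are ignored on read.
#'
#' @param map An `sm_scaffold_map`.
#' @param path File path.
#' @return `write_scaffold_map`: `path` invisibly; `read_scaffold_map`:
#'   the `sm_scaffold_map`.
#' @export
write_scaffold_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# scaffold_id\trank\tcontig_id\torientation\tcopies_placed\tprovenance",
             con)
  pl <- map$placements
  for (sid in unique(pl$scaffold_id)) {
    sp <- pl[pl$scaffold_id == sid, , drop = FALSE]
    sp <- sp[order(sp$rank), , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%s\t%s\t%d\t%s", sp$scaffold_id, sp$rank,
                       sp$contig_id, sp$orientation, sp$copies_placed,
                       sp$provenance), con)
    writeLines("", con)
  }
  if (length(map$unscaffolded))
    writeLines(sprintf("# unscaffolded: %s", map$unscaffolded), con)
  invisible(path)
}

#' @rdname write_scaffold_map
#' @export
read_scaffold_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  unsc <- sub("^#\\s*unscaffolded:\\s*", "",
              grep("^#\\s*unscaffolded:", lines, value = TRUE))
  rec <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(rec) == 0)
    return(scaffold_map(data.frame(scaffold_id = character(),
                                   rank = integer(),
                                   contig_id = character(),
                                   orientation = character(),
                                   copies_placed = integer(),
                                   provenance = character(),
                                   stringsAsFactors = FALSE), unsc))
  f <- strsplit(rec, "\t", fixed = TRUE)
  short <- which(vapply(f, length, integer(1)) < 6)
  if (length(short))
    stop("scaffold map ", path, ": record with fewer than 6 columns: ",
         rec[short[1]])
  pl <- data.frame(
    scaffold_id = vapply(f, `[`, character(1), 1),
    rank = as.integer(vapply(f, `[`, character(1), 2)),
    contig_id = vapply(f, `[`, character(1), 3),
    orientation = vapply(f, `[`, character(1), 4),
    copies_placed = as.integer(vapply(f, `[`, character(1), 5)),
    provenance = vapply(f, `[`, character(1), 6),
    stringsAsFactors = FALSE)
  if (!all(pl$orientation %in% c("+", "-")))
    stop("scaffold map ", path, ": orientation must be '+' or '-'")
  scaffold_map(pl, unsc)
}
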