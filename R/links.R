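#' Estimate the mate-pair insert-size model
#'
#' Insert sizes are measured on read pairs whose two mates map to the same
#' contig, as the outermost-coordinate span (max end - min start + 1). The
#' resulting histogram is the basis for choosing the two insert-size upper
#' bounds: mate-pair libraries typically show a main kb-scale population
#' and, frequently, a short-insert contaminant population; the two bounds
#' are read off the histogram and written into the configuration.
#'
#' The bounds themselves are user-set (echoed from `cfg`), not fitted: the
#' histogram is emitted for visual determination when they are unset.
#'
#' @param mappings Filtered mapping data.frame.
#' @param cfg An [sm_config()] object.
#' @return An object of class `sm_insert_model`: a list with `histogram`
#'   (data.frame `bin_start`, `count`), `inserts` (the raw intra-contig
#'   insert estimates), `n_pairs`, and the bounds `small_insert_upper`,
#'   `main_insert_upper`, `noisy_factor` copied from `cfg`.
#' @export
estimate_insert_model <- function(mappings, cfg = sm_config()) {
  pairs <- pair_mappings(mappings, cfg$multimap_cap)
  intra <- pairs[pairs$contig_id_a == pairs$contig_id_b, , drop = FALSE]
  if (nrow(intra) == 0)
    stop("no read pair has both mates on one contig; the insert-size ",
         "distribution cannot be estimated. Use larger contigs or set the ",
         "insert bounds manually.")
  inserts <- pmax(intra$end_a, intra$end_b) -
    pmin(intra$start_a, intra$start_b) + 1L
  bin <- cfg$histogram_bin
  bin_start <- as.integer(floor((inserts - 1) / bin) * bin + 1)
  tab <- table(bin_start)
  model <- list(
    histogram = data.frame(bin_start = as.integer(names(tab)),
                           count = as.integer(tab)),
    inserts = inserts,
    n_pairs = length(inserts),
    small_insert_upper = cfg$small_insert_upper,
    main_insert_upper = cfg$main_insert_upper,
    noisy_factor = cfg$noisy_factor)
  class(model) <- "sm_insert_model"
  model
}

#' @export
print.sm_insert_model <- function(x, ...) {
  cat(sprintf("insert-size model from %d intra-contig pairs\n", x$n_pairs))
  cat(sprintf("  median insert %.0f bp, bounds: small <= %s, main <= %s\n",
              stats::median(x$inserts), format(x$small_insert_upper),
              format(x$main_insert_upper)))
  invisible(x)
}

# Join the two mates of each pair. Multi-mapped mates expand into all
# mate1 x mate2 combinations; reads exceeding `cap` combinations are
# dropped with one summary warning (they encode unusable ambiguity).
pair_mappings <- function(mappings, cap = 4L) {
  m1 <- mappings[mappings$mate == 1L, , drop = FALSE]
  m2 <- mappings[mappings$mate == 2L, , drop = FALSE]
  pairs <- merge(m1, m2, by = "read_id", suffixes = c("_a", "_b"))
  if (nrow(pairs) == 0) return(pairs)
  combos <- table(pairs$read_id)
  over <- names(combos)[combos > cap]
  if (length(over)) {
    warning(length(over), " read pair(s) expanded beyond the multi-mapping",
            " cap (", cap, ") and were dropped")
    pairs <- pairs[!(pairs$read_id %in% over), , drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs
}

#' Build mate-pair links between contigs
#'
#' Turns mate mappings into links: one link per read pair whose two mates
#' both map. The raw set keeps everything (intra-contig pairs included, on
#' the diagonal of the raw link map). The clean set keeps only links usable
#' as adjacency evidence between different contigs:
#'
#' * intra-contig pairs are excluded;
#' * each mate must lie within `main_insert_upper` of its nearer contig
#'   end (a mate buried deeper than one insert length cannot reach a
#'   neighbouring contig);
#' * the minimal insert implied by the two end distances (their sum, i.e.
#'   the insert if the gap were zero) must not exceed
#'   `noisy_factor * main_insert_upper` — the noise rule that also discards
#'   short-insert pairs intra-contig.
#'
#' Every link (raw ones included) carries end labels: `end_*` is the
#' mate's nearer contig end (5' or 3') and `dist_*` the outer-coordinate
#' span between mate and that end. Raw links deep inside a contig are what
#' chimera detection feeds on — see [detect_chimerae()]. Links are stored
#' symmetrically with `contig_a <= contig_b` lexicographically; `pos_*` is
#' the mate's start coordinate on its contig, and `insert` the
#' outermost-coordinate span (intra-contig pairs only, NA otherwise).
#'
#' @param mappings Filtered mapping data.frame.
#' @param contigs Contig info data.frame (`contig_id`, `length`).
#' @param cfg An [sm_config()] object with both insert bounds set.
#' @return A list with data.frames `raw` and `clean`.
#' @export
build_links <- function(mappings, contigs, cfg) {
  if (is.na(cfg$main_insert_upper))
    stop("main_insert_upper is not set; determine it from the insert-size ",
         "histogram first")
  known <- mappings$contig_id %in% contigs$contig_id
  mappings <- mappings[known, , drop = FALSE]
  pairs <- pair_mappings(mappings, cfg$multimap_cap)
  len <- stats::setNames(contigs$length, contigs$contig_id)

  empty <- data.frame(read_id = character(), contig_a = character(),
                      contig_b = character(), end_a = character(),
                      end_b = character(), orient_a = character(),
                      orient_b = character(), pos_a = integer(),
                      pos_b = integer(), insert = integer(),
                      intra = logical(), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) return(list(raw = empty, clean = empty))

  # canonical role order: contig_a <= contig_b, ties broken by position
  swap <- pairs$contig_id_a > pairs$contig_id_b |
    (pairs$contig_id_a == pairs$contig_id_b &
       pairs$start_a > pairs$start_b)
  for (f in c("contig_id", "start", "end", "strand")) {
    a <- paste0(f, "_a"); b <- paste0(f, "_b")
    tmp <- pairs[[a]][swap]
    pairs[[a]][swap] <- pairs[[b]][swap]
    pairs[[b]][swap] <- tmp
  }

  intra <- pairs$contig_id_a == pairs$contig_id_b
  insert <- ifelse(intra,
                   pmax(pairs$end_a, pairs$end_b) -
                     pmin(pairs$start_a, pairs$start_b) + 1L,
                   NA_integer_)

  end_dist <- function(start, end, contig) {
    l <- unname(len[contig])
    d5 <- end                      # span from the 5' end through the mate
    d3 <- l - start + 1L           # span from the mate through the 3' end
    list(end = ifelse(d5 <= d3, "5'", "3'"), dist = pmin(d5, d3))
  }
  ea <- end_dist(pairs$start_a, pairs$end_a, pairs$contig_id_a)
  eb <- end_dist(pairs$start_b, pairs$end_b, pairs$contig_id_b)

  links <- data.frame(
    read_id = pairs$read_id,
    contig_a = pairs$contig_id_a, contig_b = pairs$contig_id_b,
    end_a = ea$end, end_b = eb$end,
    dist_a = ea$dist, dist_b = eb$dist,
    orient_a = pairs$strand_a, orient_b = pairs$strand_b,
    pos_a = pairs$start_a, pos_b = pairs$start_b,
    insert = as.integer(insert),
    intra = intra,
    stringsAsFactors = FALSE)

  min_insert <- ea$dist + eb$dist
  noisy_cap <- cfg$noisy_factor * cfg$main_insert_upper
  small_up <- if (is.na(cfg$small_insert_upper)) 0 else cfg$small_insert_upper
  clean_keep <- !intra &
    ea$dist <= cfg$main_insert_upper & eb$dist <= cfg$main_insert_upper &
    min_insert <= noisy_cap
  # short-insert exclusion where the insert is computable (same contig it
  # always is; those are already excluded — guard kept for completeness)
  clean_keep[!is.na(insert) &
               (insert <= small_up | insert > noisy_cap)] <- FALSE
  clean <- links[clean_keep, , drop = FALSE]
  rownames(links) <- rownames(clean) <- NULL
  list(raw = links, clean = clean)
}

#' Global link map
#'
#' Symmetric contig-by-contig matrix counting the read pairs linking each
#' pair of contigs. For a raw link set, intra-contig pairs appear on the
#' diagonal; a clean link set is inter-contig only, so its diagonal is zero.
#'
#' @param links A link data.frame (`raw` or `clean` from [build_links()]).
#' @param contigs Contig info data.frame fixing the matrix order.
#' @return An integer matrix with contig ids as dimnames.
#' @export
global_link_map <- function(links, contigs) {
  ids <- contigs$contig_id
  m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(links)) {
    tab <- table(factor(links$contig_a, levels = ids),
                 factor(links$contig_b, levels = ids))
    m <- m + unclass(tab)
    off <- tab; diag(off) <- 0L
    m <- m + t(unclass(off))
    storage.mode(m) <- "integer"
  }
  m
}

#' Neighborhood link map
#'
#' Like the global link map but resolved by contig end (5'/3') and mate
#' orientation: for every ordered contig pair it tallies links per
#' (own end, partner end) combination. Each unordered link contributes one
#' row count seen from each of its two contigs, so filtering on
#' `contig` gives the complete neighbourhood of that contig.
#'
#' @param links A link data.frame; rows without an assigned end on either
#'   side are ignored (only clean links carry end labels by construction).
#' @return A data.frame `contig`, `end`, `orient`, `partner`,
#'   `partner_end`, `partner_orient`, `count`.
#' @export
neighborhood_link_map <- function(links) {
  usable <- links[!is.na(links$end_a) & !is.na(links$end_b) & !links$intra,
                  , drop = FALSE]
  both <- rbind(
    data.frame(contig = usable$contig_a, end = usable$end_a,
               orient = usable$orient_a, partner = usable$contig_b,
               partner_end = usable$end_b, partner_orient = usable$orient_b,
               stringsAsFactors = FALSE),
    data.frame(contig = usable$contig_b, end = usable$end_b,
               orient = usable$orient_b, partner = usable$contig_a,
               partner_end = usable$end_a, partner_orient = usable$orient_a,
               stringsAsFactors = FALSE))
  if (nrow(both) == 0) {
    both$count <- integer()
    return(both)
  }
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(both))),
    both[, c("contig", "end", "orient", "partner", "partner_end",
             "partner_orient")],
    FUN = length)
  agg <- agg[order(agg$contig, agg$end, agg$partner, agg$partner_end,
                   agg$orient, agg$partner_orient), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Linkage-location histogram for one contig
#'
#' Bins the positions (mate start coordinates) of this contig's links and
#' counts, per bin, the links to each partner contig. The resulting profile
#' localizes chimera breakpoints: the two halves of a chimeric contig link
#' to different genomic neighbourhoods, so their partner profiles occupy
#' disjoint position ranges.
#'
#' @param contig_id Contig to profile.
#' @param links A link data.frame (use the raw set to see everything).
#' @param contigs Contig info data.frame (for the contig length).
#' @param bin Bin width in bp (default 50).
#' @return A data.frame `bin_start`, `partner`, `count` covering all bins
#'   from 1 to the contig length (zero-count bins included with partner
#'   NA when the contig has no links at all).
#' @export
linkage_location_histogram <- function(contig_id, links, contigs,
                                       bin = 50) {
  if (!contig_id %in% contigs$contig_id)
    stop("unknown contig: ", contig_id)
  clen <- contigs$length[match(contig_id, contigs$contig_id)]
  n_bins <- max(1L, as.integer(ceiling(clen / bin)))
  bins <- as.integer((seq_len(n_bins) - 1L) * bin + 1L)
  a_rows <- links$contig_a == contig_id & !links$intra
  b_rows <- links$contig_b == contig_id & !links$intra
  pos <- c(links$pos_a[a_rows], links$pos_b[b_rows])
  partner <- c(links$contig_b[a_rows], links$contig_a[b_rows])
  if (length(pos) == 0)
    return(data.frame(bin_start = bins, partner = NA_character_,
                      count = 0L, stringsAsFactors = FALSE))
  bin_start <- as.integer(floor((pos - 1) / bin) * bin + 1)
  agg <- stats::aggregate(list(count = rep(1L, length(pos))),
                          data.frame(bin_start = bin_start,
                                     partner = partner,
                                     stringsAsFactors = FALSE),
                          FUN = length)
  miss <- setdiff(bins, agg$bin_start)
  if (length(miss))
    agg <- rbind(agg, data.frame(bin_start = miss, partner = NA_character_,
                                 count = 0L, stringsAsFactors = FALSE))
  agg <- agg[order(agg$bin_start, agg$partner), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
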