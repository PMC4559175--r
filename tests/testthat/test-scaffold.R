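test_that("big/small classification is a simple length threshold", {
  contigs <- make_contigs(c("a", "b", "c"), c(4000, 3799, 10))
  cc <- classify_contigs(contigs, sm_config(main_insert_upper = 3800))
  expect_equal(cc$big, c(TRUE, FALSE, FALSE))
  cc0 <- classify_contigs(contigs, sm_config(main_insert_upper = 4000,
                                             big_contig_min = 0))
  expect_true(all(cc0$big))
  expect_error(classify_contigs(contigs, sm_config()), "not set")
})

test_that("chimera resolution splits contigs and rebases mappings", {
  contigs <- make_contigs("X", 10000, 120)
  rec <- data.frame(contig_id = "X", component_id = c("X.1", "X.2"),
                    component_start = c(1L, 5900L),
                    component_end = c(6100L, 10000L),
                    flagged = TRUE, stringsAsFactors = FALSE)
  maps <- rbind(make_mapping("m1", 1, "X", 2000, 2100),
                make_mapping("m2", 1, "X", 5900, 6000),  # midpoint 5950
                make_mapping("m3", 1, "X", 9000, 9100))
  res <- apply_chimera_resolution(contigs, maps, rec)
  expect_setequal(res$contigs$contig_id, c("X.1", "X.2"))
  expect_equal(res$contigs$length[res$contigs$contig_id == "X.1"], 6100L)
  expect_equal(res$contigs$coverage, c(120, 120))
  m <- res$mappings
  expect_equal(m$contig_id[m$read_id == "m1"], "X.1")
  expect_equal(m$start[m$read_id == "m1"], 2000L)
  # overlap region: farther from the shared boundary wins (X.1: 150 vs 51)
  expect_equal(m$contig_id[m$read_id == "m2"], "X.1")
  expect_equal(m$contig_id[m$read_id == "m3"], "X.2")
  expect_equal(m$start[m$read_id == "m3"], 9000L - 5900L + 1L)
})

test_that("ISE reconstructs a repeat-free simulated chromosome", {
  sim <- simulate_dataset(simulation_spec(rng_seed = 7))
  cfg <- sim_config(sim)
  pp <- preprocess(sim$contigs, sim$mappings, cfg)
  map <- run_ise(sim$contigs, pp$links$clean, pp$copy_numbers, cfg)
  expect_equal(length(unique(map$placements$scaffold_id)), 1L)
  expect_equal(length(map$unscaffolded), 0L)
  truth <- data.frame(contig_id = sim$truth$order$contig_id,
                      orientation = sim$truth$order$orientation,
                      stringsAsFactors = FALSE)
  got <- map_arrangement(map)
  # circular genome: rotate truth to start at the seed before comparing
  seed_at <- match(got$contig_id[1], truth$contig_id)
  rot <- function(df, k) df[c(k:nrow(df), seq_len(k - 1)), ]
  ok <- FALSE
  for (k in seq_len(nrow(truth)))
    if (same_arrangement(got, rot(truth, k))) ok <- TRUE
  expect_true(ok)
})

test_that("a multi-copy repeat longer than the insert breaks the scaffold", {
  sim <- simulate_dataset(simulation_spec(
    rng_seed = 3, repeats = data.frame(length = 1600, copies = 2)))
  cfg <- sim_config(sim)
  pp <- preprocess(sim$contigs, sim$mappings, cfg)
  expect_equal(pp$copy_numbers$copies[pp$copy_numbers$contig_id == "r01"],
               2L)
  res <- scaffold_contigs(sim$contigs, sim$mappings, pp$chimera_records,
                          pp$copy_numbers, cfg)
  expect_equal(length(unique(res$map$placements$scaffold_id)), 2L)
  expect_true("r01" %in% res$map$unscaffolded)
  # each scaffold is a contiguous run of the true order between repeats
  truth_runs <- split(
    sim$truth$order$contig_id[sim$truth$order$element != "r01"],
    cumsum(sim$truth$order$element == "r01")[
      sim$truth$order$element != "r01"])
  # circular: first and last runs are one arc
  runs <- unname(truth_runs)
  arc <- c(runs[[length(runs)]], runs[[1]])
  expected_arcs <- c(runs[-c(1, length(runs))], list(arc))
  for (sid in unique(res$map$placements$scaffold_id)) {
    got <- res$map$placements$contig_id[
      res$map$placements$scaffold_id == sid]
    hit <- any(vapply(expected_arcs, function(a)
      identical(a, got) || identical(rev(a), got), logical(1)))
    expect_true(hit, info = sid)
  }
})

test_that("splitting a planted chimera rescues the scaffold", {
  sim <- simulate_dataset(simulation_spec(rng_seed = 11, n_chimerae = 1))
  cfg <- sim_config(sim)
  pp <- preprocess(sim$contigs, sim$mappings, cfg)
  tr <- sim$truth$chimerae
  ch <- pp$chimera_records
  i <- match(tr$contig_id, ch$contig_id)
  resolved <- rbind(ch[-i, ], data.frame(
    contig_id = tr$contig_id,
    component_id = paste0(tr$contig_id, c(".1", ".2")),
    component_start = c(1L, tr$breakpoint + 1L),
    component_end = c(tr$breakpoint, ch$component_end[i]),
    flagged = TRUE, stringsAsFactors = FALSE))
  with_split <- scaffold_contigs(sim$contigs, sim$mappings, resolved,
                                 pp$copy_numbers, cfg)
  without <- scaffold_contigs(sim$contigs, sim$mappings,
                              pp$chimera_records, pp$copy_numbers, cfg)
  # resolved run recovers the full circle in one scaffold; the unsplit
  # chimera forces a fragmented result
  expect_equal(length(unique(with_split$map$placements$scaffold_id)), 1L)
  expect_equal(nrow(with_split$map$placements),
               nrow(sim$contigs) + 1L)  # chimera became two components
  expect_gt(length(unique(without$map$placements$scaffold_id)), 1L)
})

test_that("single big contig with no links is a singleton scaffold", {
  cfg <- default_cfg()
  contigs <- make_contigs("lonely", 5000)
  cn <- data.frame(contig_id = "lonely", copies = 1L)
  map <- run_ise(contigs, make_links("a", "3'", "b", "5'", 0), cn, cfg)
  expect_equal(map$placements$contig_id, "lonely")
  expect_equal(map$placements$orientation, "+")
  expect_equal(map$unscaffolded, character())
})

test_that("contradictory orientation evidence rejects the candidate", {
  cfg <- default_cfg()
  contigs <- make_contigs(c("a", "b"), c(5000, 5000))
  cn <- data.frame(contig_id = c("a", "b"), copies = 1L)
  # equal links to both ends of b: margin 0 < 2
  links <- rbind(make_links("a", "3'", "b", "5'", 4),
                 make_links("a", "3'", "b", "3'", 4, prefix = "x"))
  expect_message(map <- run_ise(contigs, links, cn, cfg),
                 "contradictory orientation")
  expect_equal(length(unique(map$placements$scaffold_id)), 2L)
})

test_that("ISE matches the exhaustive search whenever the optimum is unique", {
  cfg <- default_cfg()
  set.seed(101)
  checked <- 0L
  for (i in 1:40) {
    inst <- random_link_instance(sample(2:6, 1), cfg)
    oracle <- exhaustive_scaffold_search(inst$clean_links,
                                         inst$contigs$contig_id)
    if (!oracle$unique) next
    cn <- data.frame(contig_id = inst$contigs$contig_id, copies = 1L)
    map <- run_ise(inst$contigs, inst$clean_links, cn, cfg)
    expect_equal(length(unique(map$placements$scaffold_id)), 1L)
    expect_true(same_arrangement(map_arrangement(map),
                                 oracle$arrangement))
    checked <- checked + 1L
  }
  expect_gt(checked, 20L)
})

test_that("SCI inserts a small contig at its link-congruent junction", {
  cfg <- default_cfg()
  contigs <- make_contigs(c("A", "B", "C", "s"),
                          c(5000, 5000, 5000, 400))
  cn <- data.frame(contig_id = contigs$contig_id, copies = 1L)
  links <- rbind(make_links("A", "3'", "B", "5'", 20),
                 make_links("B", "3'", "C", "5'", 20),
                 make_links("B", "3'", "s", "5'", 8),
                 make_links("s", "3'", "C", "5'", 8))
  map <- run_ise(contigs, links, cn, cfg)
  expect_equal(map$unscaffolded, "s")
  map2 <- run_sci(map, contigs, links, cn, cfg)
  pl <- map2$placements[order(map2$placements$rank), ]
  expect_equal(pl$contig_id, c("A", "B", "s", "C"))
  expect_equal(pl$provenance, c("ISE", "ISE", "SCI", "ISE"))
  expect_equal(pl$orientation[3], "+")
  expect_equal(map2$unscaffolded, character())
})

test_that("SCI never adds a contig at a scaffold edge", {
  cfg <- default_cfg()
  contigs <- make_contigs(c("A", "B", "s"), c(5000, 5000, 400))
  # s is multi-copy so ISE leaves it to SCI
  cn <- data.frame(contig_id = contigs$contig_id, copies = c(1L, 1L, 2L))
  # s links only to the outward (5') end of the first placement
  links <- rbind(make_links("A", "3'", "B", "5'", 20),
                 make_links("s", "3'", "A", "5'", 15))
  map <- run_sci(run_ise(contigs, links, cn, cfg), contigs, links, cn,
                 cfg)
  expect_equal(map$unscaffolded, "s")
  expect_equal(nrow(map$placements), 2L)
})

test_that("SCI places a 2-copy repeat at two junctions with its copy number", {
  sim <- simulate_dataset(simulation_spec(
    rng_seed = 8, repeats = data.frame(length = 700, copies = 2)))
  cfg <- sim_config(sim)
  pp <- preprocess(sim$contigs, sim$mappings, cfg)
  res <- scaffold_contigs(sim$contigs, sim$mappings, pp$chimera_records,
                          pp$copy_numbers, cfg)
  pl <- res$map$placements
  rep_pl <- pl[pl$contig_id == "r01", ]
  expect_equal(nrow(rep_pl), 2L)
  expect_equal(unique(rep_pl$provenance), "SCI")
  expect_equal(unique(rep_pl$copies_placed), 2L)
  # inserted at the true junctions: neighbours in the map must be the
  # true genomic neighbours of each repeat copy
  ord <- sim$truth$order
  true_nbrs <- lapply(which(ord$element == "r01"), function(i) {
    n <- nrow(ord)
    sort(c(ord$contig_id[((i - 2) %% n) + 1],
           ord$contig_id[(i %% n) + 1]))
  })
  for (r in seq_len(nrow(rep_pl))) {
    sp <- pl[pl$scaffold_id == rep_pl$scaffold_id[r], ]
    sp <- sp[order(sp$rank), ]
    at <- which(sp$contig_id == "r01")[
      which(sp$rank[sp$contig_id == "r01"] == rep_pl$rank[r])]
    got_nbrs <- sort(c(sp$contig_id[at - 1], sp$contig_id[at + 1]))
    expect_true(any(vapply(true_nbrs, identical, logical(1), got_nbrs)))
  }
})

test_that("scaffolding conserves contigs and is deterministic", {
  sim <- simulate_dataset(simulation_spec(
    rng_seed = 19, repeats = data.frame(length = 1600, copies = 2)))
  cfg <- sim_config(sim)
  pp <- preprocess(sim$contigs, sim$mappings, cfg)
  run <- function() scaffold_contigs(sim$contigs, sim$mappings,
                                     pp$chimera_records, pp$copy_numbers,
                                     cfg)
  r1 <- run(); r2 <- run()
  # conservation: every contig placed or listed, single-copies at most once
  all_ids <- c(r1$map$placements$contig_id, r1$map$unscaffolded)
  expect_setequal(unique(all_ids), sim$contigs$contig_id)
  tab <- table(r1$map$placements$contig_id)
  copies <- setNames(pp$copy_numbers$copies, pp$copy_numbers$contig_id)
  expect_true(all(tab <= copies[names(tab)]))
  # determinism: byte-identical map files
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_scaffold_map(r1$map, f1)
  write_scaffold_map(r2$map, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("flipping every end label flips every placement orientation", {
  # relabelling 5'<->3' on all links is a per-contig strand flip of the
  # underlying genome: the recovered order must be unchanged and every
  # orientation inverted (up to the usual global reversal)
  cfg <- default_cfg()
  set.seed(55)
  flip <- c("5'" = "3'", "3'" = "5'")
  for (i in 1:5) {
    inst <- random_link_instance(sample(3:6, 1), cfg, noise_links = 0)
    cn <- data.frame(contig_id = inst$contigs$contig_id, copies = 1L)
    mirrored <- inst$clean_links
    mirrored$end_a <- unname(flip[inst$clean_links$end_a])
    mirrored$end_b <- unname(flip[inst$clean_links$end_b])
    m1 <- run_ise(inst$contigs, inst$clean_links, cn, cfg)
    m2 <- run_ise(inst$contigs, mirrored, cn, cfg)
    expected <- map_arrangement(m1)
    expected$orientation <- unname(
      c("+" = "-", "-" = "+")[expected$orientation])
    expect_true(same_arrangement(expected, map_arrangement(m2)))
  }
})
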