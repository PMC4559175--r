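test_that("intra-contig insert estimate is the outermost-coordinate span", {
  contigs <- make_contigs("c1", 50000)
  maps <- make_pair("p1", "c1", 100, 200, "c1", 3900, 4000)
  model <- estimate_insert_model(maps, sm_config(histogram_bin = 50))
  expect_equal(model$inserts, 3901L)  # 4000 - 100 + 1, inclusive span
  expect_equal(model$n_pairs, 1L)
  expect_error(
    estimate_insert_model(make_mapping("q", 1, "c1", 1, 100), sm_config()),
    "no read pair")
})

test_that("insert histogram recovers the generating distribution", {
  sim <- simulate_dataset(simulation_spec(
    genome_length = 50000, n_contigs = 1, circular = FALSE,
    small_frac = 0, main_mean = 4000, main_sd = 300, n_pairs = 4000,
    rng_seed = 21))
  model <- estimate_insert_model(sim$mappings,
                                 sm_config(histogram_bin = 50))
  h <- model$histogram
  mode_bin <- h$bin_start[which.max(h$count)]
  expect_gt(mode_bin, 3800)
  expect_lt(mode_bin, 4200)
  expect_gte(sum(model$inserts <= 5000) / length(model$inserts), 0.99)
})

test_that("bimodal insert mixture shows two modes and an empty valley", {
  sim <- simulate_dataset(simulation_spec(
    genome_length = 50000, n_contigs = 1, circular = FALSE,
    small_frac = 0.1, small_mean = 250, small_sd = 20,
    main_mean = 4000, main_sd = 300, n_pairs = 5000, rng_seed = 22))
  model <- estimate_insert_model(sim$mappings,
                                 sm_config(histogram_bin = 50))
  ins <- model$inserts
  expect_gt(sum(ins < 1000), 0.05 * length(ins))
  expect_gt(sum(ins > 3000), 0.8 * length(ins))
  # empty valley between the modes (>35 sd above small, >4.5 sd below main)
  expect_equal(sum(ins >= 1000 & ins <= 2600), 0)
  frac_small <- mean(ins < 1000)
  expect_lt(abs(frac_small - 0.1), 0.02)
})

test_that("clean links require end proximity and plausible implied insert", {
  cfg <- sm_config(small_insert_upper = 0, main_insert_upper = 4000)
  contigs <- make_contigs(c("big1", "big2"), c(100000, 100000))
  maps <- rbind(
    # mates near facing ends: clean evidence (c1 3' <-> c2 5')
    make_pair("ok", "big1", 99000, 99100, "big2", 500, 600),
    # both mates 40 kb from any end: cannot witness adjacency
    make_pair("mid", "big1", 40000, 40100, "big2", 40000, 40100),
    # implied minimal insert 5.2 kb + 4.9 kb >> 1.5 x 4000: noise
    make_pair("far", "big1", 94900, 95000, "big2", 5100, 5200))
  links <- build_links(maps, contigs, cfg)
  expect_equal(nrow(links$raw), 3L)
  expect_equal(links$clean$read_id, "ok")
  expect_equal(links$clean$end_a, "3'")
  expect_equal(links$clean$end_b, "5'")
  expect_true(all(c("mid", "far") %in% links$raw$read_id))
})

test_that("clean link set is a subset of raw and maps are symmetric", {
  sim <- simulate_dataset(simulation_spec(rng_seed = 31))
  cfg <- sim_config(sim)
  links <- build_links(sim$mappings, sim$contigs, cfg)
  expect_true(all(links$clean$read_id %in% links$raw$read_id))
  expect_lt(nrow(links$clean), nrow(links$raw))
  g <- global_link_map(links$clean, sim$contigs)
  expect_true(isSymmetric(g))
  expect_true(all(diag(g) == 0))
  graw <- global_link_map(links$raw, sim$contigs)
  expect_true(isSymmetric(graw))
  expect_gt(sum(diag(graw)), 0)  # intra-contig pairs on the diagonal
  # order invariance
  perm <- sample(nrow(links$clean))
  expect_equal(global_link_map(links$clean[perm, ], sim$contigs), g)
})

test_that("neighborhood map is concentrated where the links are", {
  links <- make_links("c1", "3'", "c2", "5'", 10)
  nm <- neighborhood_link_map(links)
  expect_equal(sum(nm$count), 20L)  # each link seen from both contigs
  from_c1 <- nm[nm$contig == "c1", ]
  expect_equal(unique(from_c1$end), "3'")
  expect_equal(unique(from_c1$partner_end), "5'")
  expect_equal(sum(from_c1$count), 10L)
})

test_that("linkage-location histogram bins positions per partner", {
  contigs <- make_contigs(c("c1", "a", "b"), c(1000, 5000, 5000))
  links <- rbind(make_links("a", "3'", "c1", "5'", 4),
                 make_links("b", "5'", "c1", "3'", 6))
  links$pos_b[links$contig_a == "a"] <- 120L   # positions on c1
  links$pos_b[links$contig_a == "b"] <- 880L
  h <- linkage_location_histogram("c1", links, contigs, bin = 50)
  expect_equal(length(unique(h$bin_start)), 20L)  # 1000 / 50
  expect_equal(h$count[h$partner %in% "a" & !is.na(h$partner)], 4L)
  expect_equal(h$bin_start[which(h$partner %in% "a")], 101L)
  expect_equal(h$bin_start[which(h$partner %in% "b")], 851L)
  expect_error(linkage_location_histogram("nope", links, contigs), "unknown")
  h0 <- linkage_location_histogram("c1", links[0, ], contigs, bin = 50)
  expect_true(all(h0$count == 0))
})

test_that("chimera detector needs supported partners, not stray links", {
  cfg <- default_cfg()
  contigs <- make_contigs(c("X", "A", "B", "C"),
                          c(5000, 5000, 5000, 5000))
  cn <- data.frame(contig_id = contigs$contig_id, copies = 1L)
  # two honest neighbours plus one single stray link: not flagged
  links <- rbind(make_links("A", "3'", "X", "5'", 10),
                 make_links("X", "3'", "B", "5'", 10),
                 make_links("X", "3'", "C", "5'", 1))
  rec <- detect_chimerae(links, contigs, cn, cfg)
  expect_false(rec$flagged[rec$contig_id == "X"])
  # raise the stray to the support threshold: flagged (2 partners, one end)
  links2 <- rbind(links, make_links("X", "3'", "C", "5'", 4,
                                    prefix = "more"))
  rec2 <- detect_chimerae(links2, contigs, cn, cfg)
  expect_true(rec2$flagged[rec2$contig_id == "X"])
  # a multi-copy contig with the same neighbourhood is exempt
  cn3 <- cn; cn3$copies[cn3$contig_id == "X"] <- 2L
  rec3 <- detect_chimerae(links2, contigs, cn3, cfg)
  expect_false(rec3$flagged[rec3$contig_id == "X"])
})

test_that("chimera detector is right on simulated genomes", {
  # sensitivity: every planted chimera flagged
  sim <- simulate_dataset(simulation_spec(rng_seed = 11, n_chimerae = 1))
  pp <- preprocess(sim$contigs, sim$mappings, sim_config(sim))
  expect_equal(
    pp$chimera_records$contig_id[pp$chimera_records$flagged],
    sim$truth$chimerae$contig_id)
  # specificity: clean genome, nothing flagged
  sim2 <- simulate_dataset(simulation_spec(rng_seed = 12))
  pp2 <- preprocess(sim2$contigs, sim2$mappings, sim_config(sim2))
  expect_equal(sum(pp2$chimera_records$flagged), 0L)
})

test_that("copy numbers are coverage ratios, half-up rounded, floored at 1", {
  contigs <- make_contigs(c("big", "X", "Y"), c(357000, 4000, 5000),
                          c(800, 1650, 790))
  cn <- estimate_copy_numbers(contigs)
  expect_equal(cn$copies[cn$contig_id == "big"], 1L)
  expect_equal(cn$copies[cn$contig_id == "X"], 2L)   # round(2.06)
  expect_equal(cn$copies[cn$contig_id == "Y"], 1L)   # round(0.99)
  contigs$coverage[1] <- 0
  expect_error(estimate_copy_numbers(contigs), "zero coverage")
})

test_that("copy-number recovery is exact up to 4 copies under coverage noise", {
  # rounding to the nearest integer tolerates a ratio perturbation below
  # 1/(2*copies): 12.5 % for 4 copies. Realistic per-contig coverage noise
  # at hundreds-fold depth is a few percent; the truncation keeps every
  # draw inside the guarantee.
  set.seed(77)
  for (rep in 1:20) {
    true_copies <- c(1L, sample(1:4, 6, replace = TRUE))
    noise <- exp(pmax(pmin(rnorm(7, 0, 0.03), 0.06), -0.06))
    contigs <- make_contigs(sprintf("c%d", 1:7),
                            c(50000, sample(3000:9000, 6)),
                            100 * true_copies * noise)
    cn <- estimate_copy_numbers(contigs)
    expect_equal(cn$copies, true_copies)
  }
})

test_that("preprocess without insert bounds writes histogram and stops", {
  sim <- simulate_dataset(simulation_spec(rng_seed = 13))
  cfg <- sm_config()  # bounds NA
  out <- withr::local_tempdir()
  expect_error(preprocess(sim$contigs, sim$mappings, cfg, out_dir = out),
               "bounds are not set")
  expect_true(file.exists(
    file.path(out, cfg$output_names[["insert_histogram"]])))
})

test_that("preprocess --dumpfiles writes the full diagnostic set", {
  sim <- simulate_dataset(simulation_spec(rng_seed = 14))
  cfg <- sim_config(sim)
  out <- withr::local_tempdir()
  pp <- preprocess(sim$contigs, sim$mappings, cfg, out_dir = out,
                   dumpfiles = TRUE)
  on <- cfg$output_names
  for (role in c("chimera", "copy_number", "insert_histogram",
                 "global_link_map", "clean_global_link_map",
                 "neighborhood_link_map", "clean_neighborhood_link_map",
                 "linkage_location"))
    expect_true(file.exists(file.path(out, on[[role]])), info = role)
  # the two verdict files re-import to what preprocess computed
  expect_equal(read_chimera_file(file.path(out, on[["chimera"]])),
               pp$chimera_records)
  expect_equal(read_copy_numbers(file.path(out, on[["copy_number"]])),
               pp$copy_numbers)
})
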