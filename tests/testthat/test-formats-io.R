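test_that("contig info table parses, filters on coverage, rejects bad input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\t800\t357000", "c2\t1600\t4000"), f)
  cfg <- sm_config(main_insert_upper = 4000)
  ci <- read_contig_info(f, cfg)
  expect_equal(ci$contig_id, c("c1", "c2"))
  expect_equal(ci$length, c(357000L, 4000L))
  expect_equal(ci$coverage, c(800, 1600))

  # contaminant filtering: a low-coverage row is dropped
  writeLines(c("c1\t800\t357000", "c2\t1600\t4000", "bact1\t40\t9000"), f)
  cfg500 <- sm_config(main_insert_upper = 4000, min_contig_coverage = 500)
  expect_equal(nrow(read_contig_info(f, cfg500)), 2L)

  writeLines(character(), f)
  expect_warning(empty <- read_contig_info(f, cfg), "empty")
  expect_equal(nrow(empty), 0L)

  writeLines(c("c1\t800"), f)
  expect_error(read_contig_info(f, cfg), "line 1")
  writeLines(c("c1\t800\tabc"), f)
  expect_error(read_contig_info(f, cfg), "non-numeric")
  writeLines(c("c1\t800\t100", "c1\t900\t200"), f)
  expect_error(read_contig_info(f, cfg), "duplicate")
})

test_that("parsing tolerates CRLF line endings and blank lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeBin(charToRaw("c1\t800\t357000\r\n\r\nc2\t1600\t4000\r\n"), f)
  ci <- read_contig_info(f, sm_config(main_insert_upper = 4000))
  expect_equal(ci$contig_id, c("c1", "c2"))
})

test_that("SAM and 7-column dialects of one mapping set yield the same links", {
  contigs <- make_contigs(c("c1", "c2"), c(3000, 3000))
  maps <- rbind(make_pair("p1", "c1", 2800, 2900, "c2", 200, 300),
                make_pair("p2", "c1", 2700, 2800, "c2", 100, 200),
                make_pair("p3", "c1", 100, 200, "c1", 900, 1000))
  tab <- withr::local_tempfile(fileext = ".tsv")
  sam <- withr::local_tempfile(fileext = ".sam")
  write_mappings_tab7(maps, tab)
  write_mappings_sam(maps, contigs, sam)
  cfg <- default_cfg()
  m_tab <- read_mapping_table(tab, "auto", cfg)
  m_sam <- read_mapping_table(sam, "auto", cfg)
  expect_equal(sniff_mapping_dialect(sam), "sam")
  expect_equal(sniff_mapping_dialect(tab), "tab7")
  key <- function(m) {
    m <- m[order(m$read_id, m$mate), ]
    paste(m$read_id, m$mate, m$contig_id, m$start, m$end, m$strand)
  }
  expect_equal(key(m_tab), key(m_sam))
  l_tab <- build_links(m_tab, contigs, cfg)
  l_sam <- build_links(m_sam, contigs, cfg)
  expect_equal(l_tab$clean[order(l_tab$clean$read_id), ],
               l_sam$clean[order(l_sam$clean$read_id), ],
               ignore_attr = TRUE)
})

test_that("unmapped and secondary SAM records are skipped", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:c1\tLN:1000",
    "r1\t65\tc1\t1\t60\t100M\t*\t0\t0\t*\t*\tNM:i:0",
    "r1\t129\tc1\t500\t60\t100M\t*\t0\t0\t*\t*\tNM:i:1",
    "r2\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r3\t321\tc1\t700\t60\t100M\t*\t0\t0\t*\t*\tNM:i:0"), sam)
  m <- read_mapping_table(sam, "sam", sm_config())
  expect_equal(sort(m$read_id), c("r1", "r1"))
  expect_equal(m$mate[order(m$start)], c(1L, 2L))
  expect_equal(m$end - m$start + 1L, c(100L, 100L))
})

test_that("accuracy filter keeps full-length 0-3 mismatch hits only", {
  maps <- rbind(make_mapping("a", 1, "c1", 1, 100, mismatches = 3),
                make_mapping("b", 1, "c1", 1, 100, mismatches = 4),
                make_mapping("c", 1, "c1", 1, 100, mismatches = 0,
                             full_length = FALSE))
  kept <- filter_mappings(maps, 3, TRUE)
  expect_equal(kept$read_id, "a")
  # order preserved, clipping filter alone
  kept2 <- filter_mappings(maps, Inf, TRUE)
  expect_equal(kept2$read_id, c("a", "b"))
  # absent mismatch info must not silently pass the filter
  maps$mismatches <- NA_integer_
  expect_error(filter_mappings(maps, 3, TRUE), "disable")
})

test_that("configuration round-trips through the key=value file", {
  cfg <- sm_config(small_insert_upper = 600, main_insert_upper = 4000,
                   min_link_support = 7, min_contig_coverage = 500)
  f <- withr::local_tempfile(fileext = ".txt")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back[.config_scalar_fields],
               cfg[.config_scalar_fields])
  expect_equal(back$map_columns, cfg$map_columns)
  expect_equal(back$output_names, cfg$output_names)
  # unknown keys warn but do not fail (hand-edited file tolerance)
  writeLines(c(readLines(f), "someone_elses_key = 1"), f)
  expect_warning(read_config(f), "unknown configuration key")
})

test_that("chimera and copy-number files round-trip and validate", {
  rec <- data.frame(contig_id = c("X", "X", "Y"),
                    component_id = c("X.1", "X.2", "Y"),
                    component_start = c(1L, 5900L, 1L),
                    component_end = c(6100L, 10000L, 2000L),
                    flagged = c(TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_chimera_file(rec, f)
  expect_equal(read_chimera_file(f), rec)  # 200 bp overlap accepted

  # gap between components is rejected
  bad <- rec
  bad$component_start[2] <- 6200L
  write_chimera_file(bad, f)
  expect_error(read_chimera_file(f), "gap")

  cn <- data.frame(contig_id = c("X", "Y"), copies = c(2L, 1L),
                   stringsAsFactors = FALSE)
  write_copy_numbers(cn, f)
  expect_equal(read_copy_numbers(f), cn)
  writeLines(c("contig_id\tcopies", "X\t0"), f)
  expect_error(read_copy_numbers(f), ">= 1")
})

test_that("scaffold map file round-trips including unscaffolded list", {
  pl <- data.frame(
    scaffold_id = c("scaffold_1", "scaffold_1", "scaffold_2"),
    rank = c(1L, 2L, 1L),
    contig_id = c("c2", "c1", "c3"),
    orientation = c("+", "-", "+"),
    copies_placed = c(1L, 1L, 2L),
    provenance = c("ISE", "ISE", "SCI"),
    stringsAsFactors = FALSE)
  map <- scaffold_map(pl, unscaffolded = c("c9", "c10"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scaffold_map(map, f)
  back <- read_scaffold_map(f)
  expect_equal(back$placements, map$placements)
  expect_equal(back$unscaffolded, map$unscaffolded)
  # ranks must be consecutive from 1
  bad <- pl; bad$rank[2] <- 3L
  expect_error(scaffold_map(bad), "consecutive")
})
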