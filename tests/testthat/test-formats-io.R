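test_that("gene tables get 0-based start-sorted ranks with stable ties", {
  f <- write_tmp_lines(c(
    "a\tchr1\t100\t110\t+",
    "b\tchr1\t50\t60\t+",
    "c\tchr1\t200\t210\t-"
  ))
  g <- read_gene_positions(f, "tsv")
  expect_equal(g$rank[match(c("a", "b", "c"), g$gene_id)], c(1L, 0L, 2L))
  # ties on start broken by end then gene id
  f2 <- write_tmp_lines(c(
    "z\tchr1\t100\t120\t+",
    "y\tchr1\t100\t110\t+",
    "x\tchr1\t100\t110\t+"
  ))
  g2 <- read_gene_positions(f2, "tsv")
  expect_equal(g2$gene_id[order(g2$rank)], c("x", "y", "z"))
})

test_that("gene readers parse all records across dialects and reject bad input", {
  fx <- cached_fixture("balanced_small", scenario = "balanced",
                       n_chromosomes = 3, genes_per_chromosome = 300,
                       seed = 11)
  bed <- read_gene_positions(fx$files[["reference_bed"]], "bed")
  expect_equal(nrow(bed), 3 * 300)
  gff <- read_gene_positions(fx$files[["reference_gff3"]], "gff3")
  expect_equal(nrow(gff), 3 * 300)
  # identical coordinates and ranks from both carriers
  expect_equal(
    dplyr::arrange(tibble::as_tibble(bed), gene_id)[, c("gene_id", "start", "rank")],
    dplyr::arrange(tibble::as_tibble(gff), gene_id)[, c("gene_id", "start", "rank")]
  )
  # duplicate ids rejected
  fdup <- write_tmp_lines(c("a\tchr1\t1\t5\t+", "a\tchr1\t10\t15\t+"))
  expect_error(read_gene_positions(fdup, "tsv"), "duplicate")
  # empty file rejected
  fempty <- write_tmp_lines(character(0))
  expect_error(read_gene_positions(fempty, "tsv"), "empty")
  # unparseable line named
  fbad <- write_tmp_lines(c("a\tchr1\t1\t5\t+", "oops"))
  expect_error(read_gene_positions(fbad, "tsv"), "line 2")
})

test_that("anchor TSV reading infers blocks and orientation", {
  ref <- mini_ref()
  qry <- mini_qry()
  f <- write_tmp_lines(c(
    "g1\tq1\tb1", "g2\tq2\tb1", "g3\tq3\tb1",
    "g5\tq6\tb2", "g6\tq5\tb2"
  ))
  an <- read_collinearity(f, "tsv", ref, qry)
  expect_equal(nrow(an), 5)
  b <- summarize_blocks(an)
  expect_equal(b$orientation[b$block_id == "b1"], "+")
  expect_equal(b$orientation[b$block_id == "b2"], "-")
  expect_equal(b$ref_lo[b$block_id == "b1"], 0L)
  expect_equal(b$ref_hi[b$block_id == "b1"], 3L) # half-open
  # unknown gene id errors with offender named
  fbad <- write_tmp_lines(c("g1\tq1\tb1", "gX\tq2\tb1"))
  expect_error(read_collinearity(fbad, "tsv", ref, qry), "gX")
  # single-anchor block kept with warning
  fone <- write_tmp_lines(c("g1\tq1\tb1"))
  expect_warning(an1 <- read_collinearity(fone, "tsv", ref, qry),
                 "< 2 anchors")
  expect_equal(nrow(an1), 1)
})

test_that("MCScanX dialect round-trips through the fixture writer", {
  fx <- cached_fixture("balanced_small", scenario = "balanced",
                       n_chromosomes = 3, genes_per_chromosome = 300,
                       seed = 11)
  ref <- read_gene_positions(fx$files[["reference_bed"]], "bed")
  qry <- read_gene_positions(fx$files[["query_genes"]], "tsv")
  mcs <- read_collinearity(fx$files[["collinearity"]], "mcscanx", ref, qry)
  tsv <- read_collinearity(fx$files[["anchors_tsv"]], "tsv", ref, qry)
  expect_equal(nrow(mcs), nrow(tsv))
  expect_setequal(mcs$block_id, tsv$block_id)
  m <- dplyr::arrange(tibble::as_tibble(mcs), block_id, ref_rank)
  t <- dplyr::arrange(tibble::as_tibble(tsv), block_id, ref_rank)
  expect_equal(m$ref_gene, t$ref_gene)
  expect_equal(m$qry_gene, t$qry_gene)
  # anchor count per block matches header N
  hdr <- grep("^## Alignment",
              readLines(fx$files[["collinearity"]]), value = TRUE)
  n_declared <- sum(as.integer(sub(".*N=(\\d+).*", "\\1", hdr)))
  expect_equal(nrow(mcs), n_declared)
})

test_that("result reports round-trip losslessly", {
  p <- random_profile_case(401)
  res <- pindex_pair(p$profile)
  f <- tempfile()
  write_pindex_result(res, f)
  back <- read_pindex_result(f)
  expect_equal(back$pindex, res$pindex, tolerance = 1e-12)
  expect_equal(back$status, res$status)
  expect_equal(back$chromosomes$term, res$chromosomes$term,
               tolerance = 1e-12)
  expect_lt(abs(sum(back$chromosomes$weight) - 1), 1e-9)
  # undefined result is recorded as such
  prof0 <- retention_profile(tibble::tibble(
    chrom = "c1", window = rep(1:5, 2), n_genes = 100L,
    track = rep(1:2, each = 5), retention = rep(0.8, 10)), M = 100)
  res0 <- pindex_pair(prof0)
  f0 <- tempfile()
  write_pindex_result(res0, f0)
  expect_equal(read_pindex_result(f0)$status, "undefined")
})

test_that("the packaged event catalog matches its transcription", {
  ev <- read_event_table()
  expect_equal(dplyr::n_distinct(ev$event), 24)
  expect_equal(nrow(ev), 57)
  e9 <- ev[ev$event == 9, ]
  expect_equal(nrow(e9), 1)
  expect_equal(e9$checked_genome, "G. max")
  expect_equal(e9$reference_genome, "M. truncatula")
  expect_equal(e9$pindex, 0.17)
  expect_equal(e9$printed_nature, "Auto")
  e7 <- ev[ev$event == 7, ]
  expect_equal(e7$checked_genome, "G. hirsutum")
  expect_equal(e7$reference_genome, "G. raimondii")
  expect_equal(e7$pindex, 0.70)
  e13 <- ev[ev$event == 13, ]
  expect_equal(e13$checked_genome, "V. vinifera")
  expect_equal(e13$pindex, 0.79)
  expect_equal(sort(ev$pindex[ev$event == 1]), c(0.82, 0.85))
  # events 3 and 4 printed without a nature label
  expect_true(all(is.na(ev$printed_nature[ev$event %in% c(3, 4)])))
  expect_true(all(!is.na(ev$printed_nature[!ev$event %in% c(3, 4)])))
  # packaged file is exactly what the generator writes
  f <- tempfile()
  make_event_table_fixture(f)
  expect_identical(
    readLines(f),
    readLines(system.file("extdata", "polyploidy_events.tsv",
                          package = "pindexr"))
  )
  # malformed fixture rejected
  fbad <- write_tmp_lines(c("event\tpindex", "1\t0.5"))
  expect_error(read_event_table(fbad), "malformed")
})
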