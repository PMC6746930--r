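ref_100 <- function() {
  f <- write_tmp_lines(sprintf("r%d\tchr1\t%d\t%d\t+",
                               0:99, 0:99 * 10 + 1, 0:99 * 10 + 5))
  read_gene_positions(f, "tsv", genome_label = "ref100")
}

anchors_for <- function(ranks, block, qchrom = "qcA", ref) {
  tibble::tibble(
    block_id = block,
    ref_gene = paste0("r", ranks),
    ref_chrom = "chr1",
    ref_rank = as.integer(ranks),
    qry_gene = paste0(block, "_", ranks),
    qry_chrom = qchrom,
    qry_rank = seq_along(ranks) - 1L
  )
}

test_that("greedy tiling places disjoint blocks together and overlaps apart", {
  ref <- ref_100()
  an <- dplyr::bind_rows(
    anchors_for(0:29, "b_big", "qcA", ref),    # 30 anchors
    anchors_for(50:69, "b_right", "qcB", ref), # disjoint from b_big
    anchors_for(0:24, "b_over", "qcC", ref)    # fully inside b_big span
  )
  asg <- partition_subgenomes(an, ref, S = 2)
  placed <- dplyr::filter(tibble::as_tibble(asg), !is.na(qry_gene))
  track_of <- function(b) unique(placed$track[placed$block_id == b])
  expect_equal(track_of("b_big"), 1L)
  expect_equal(track_of("b_right"), 1L) # disjoint -> lowest-index track
  expect_equal(track_of("b_over"), 2L)  # overlaps track 1 -> next track
})

test_that("partitioning is deterministic and one gene per rank and track", {
  fx <- cached_fixture("biased_mid", scenario = "biased",
                       n_chromosomes = 4, genes_per_chromosome = 600,
                       seed = 5, shatter = TRUE)
  ref <- read_gene_positions(fx$files[["reference_bed"]], "bed")
  qry <- read_gene_positions(fx$files[["query_genes"]], "tsv")
  an <- read_collinearity(fx$files[["anchors_tsv"]], "tsv", ref, qry)
  a1 <- partition_subgenomes(an, ref, S = 2)
  a2 <- partition_subgenomes(an, ref, S = 2)
  expect_identical(tibble::as_tibble(a1), tibble::as_tibble(a2))
  dup <- tibble::as_tibble(a1) |>
    dplyr::filter(!is.na(qry_gene)) |>
    dplyr::count(ref_chrom, ref_rank, track) |>
    dplyr::filter(n > 1)
  expect_equal(nrow(dup), 0)
})

test_that("shattered-block fixtures are partitioned back into their subgenomes", {
  for (scen in c("balanced", "biased")) {
    fx <- cached_fixture(paste0(scen, "_shatter"), scenario = scen,
                         n_chromosomes = 6, genes_per_chromosome = 800,
                         seed = 23, shatter = TRUE)
    ref <- read_gene_positions(fx$files[["reference_bed"]], "bed")
    qry <- read_gene_positions(fx$files[["query_genes"]], "tsv")
    an <- read_collinearity(fx$files[["anchors_tsv"]], "tsv", ref, qry)
    asg <- partition_subgenomes(an, ref, S = 2)
    expect_gte(subgenome_recovery(asg, fx$truth), 0.95)
  }
})

test_that("a missing third homoeolog leaves a track empty with a warning", {
  ref <- ref_100()
  an <- dplyr::bind_rows(
    anchors_for(0:49, "bA", "qcA", ref),
    anchors_for(0:44, "bB", "qcB", ref)
  )
  expect_warning(asg <- partition_subgenomes(an, ref, S = 3),
                 "track\\(s\\) with no placed block: 3")
  placed <- dplyr::filter(tibble::as_tibble(asg), !is.na(qry_gene))
  expect_setequal(unique(placed$track), c(1L, 2L))
  expect_error(partition_subgenomes(an, ref, S = 1), "S must be >= 2")
})

test_that("dominance ranks tracks by retention with deterministic ties", {
  ref <- ref_100()
  an <- dplyr::bind_rows(
    anchors_for(0:59, "bA", "qcA", ref),  # 60 retained
    anchors_for(0:29, "bB", "qcB", ref)   # 30 retained
  )
  asg <- label_dominance(partition_subgenomes(an, ref, S = 2))
  dom <- attr(asg, "dominance")
  expect_equal(dom$retained[dom$track == 1], 60L)
  expect_equal(dominance_order(asg), c(1L, 2L))
  # exact tie keeps input track order
  asg_tie <- as_subgenome_assignment(tibble::tibble(
    ref_chrom = "chr1", ref_rank = rep(0:29, 2),
    track = rep(1:2, each = 30), qry_gene = "x"
  ), ref, S = 2)
  expect_equal(dominance_order(asg_tie), c(1L, 2L))
  # biased fixture: dominant track is the high-retention planted subgenome
  fx <- cached_fixture("biased_mid", scenario = "biased",
                       n_chromosomes = 4, genes_per_chromosome = 600,
                       seed = 5, shatter = TRUE)
  ref_fx <- read_gene_positions(fx$files[["reference_bed"]], "bed")
  qry_fx <- read_gene_positions(fx$files[["query_genes"]], "tsv")
  an_fx <- read_collinearity(fx$files[["anchors_tsv"]], "tsv", ref_fx, qry_fx)
  asg_fx <- label_dominance(partition_subgenomes(an_fx, ref_fx, S = 2))
  dominant <- dominance_order(asg_fx)[1]
  placed <- tibble::as_tibble(asg_fx) |>
    dplyr::filter(!is.na(qry_gene), track == dominant) |>
    dplyr::left_join(dplyr::select(fx$truth, qry_gene, subgenome),
                     by = "qry_gene")
  # planted subgenome 1 has retention 0.75 vs 0.40
  expect_equal(as.integer(names(which.max(table(placed$subgenome)))), 1L)
})
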