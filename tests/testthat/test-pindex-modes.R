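make_triples <- function(n_regions = 6, genes = 400, retention = 0.7,
                         seed = 99) {
  set.seed(seed)
  purrr::map(seq_len(n_regions), function(i) {
    tibble::tibble(
      triple_id = paste0("t", i),
      pos = seq_len(genes),
      r1 = as.vector(simulate_losses(genes, retention)),
      r2 = as.vector(simulate_losses(genes, retention)),
      r3 = as.vector(simulate_losses(genes, retention))
    )
  }) |> purrr::list_rbind()
}

test_that("self-reference mode skips genes lost from the internal reference", {
  # 120 positions; reference copy misses positions 1-20, which both other
  # copies retain: those positions must not reach any window
  tr <- tibble::tibble(
    triple_id = "t1", pos = 1:120,
    r1 = c(rep(FALSE, 20), rep(TRUE, 100)),
    r2 = TRUE,
    r3 = rep(c(TRUE, FALSE), 60)
  )
  res <- pindex_selfref(tr, M = 100, min_last_window = 0.5)
  # only the 100 reference-retained positions are windowed
  expect_equal(sum(res$chromosomes$n_windows), 1L)
  expect_equal(res$chromosomes$n_informative, 1L)
  # compared copies identical to the reference -> nothing informative
  tr_same <- tibble::tibble(triple_id = "t1", pos = 1:200,
                            r1 = TRUE, r2 = TRUE, r3 = TRUE)
  expect_equal(pindex_selfref(tr_same, M = 100)$status, "undefined")
  expect_error(pindex_selfref(dplyr::select(tr, -r3), regions = c("r1", "r2")),
               "3 region")
})

test_that("rotation over homogeneous loss gives three concordant estimates", {
  tr <- make_triples(n_regions = 6, genes = 400, retention = 0.7, seed = 99)
  rot <- pindex_selfref(tr, rotate = TRUE, M = 100)
  expect_equal(nrow(rot$summary), 3)
  expect_lt(diff(range(rot$summary$pindex)), 0.1)
  expect_equal(rot$mean_pindex, mean(rot$summary$pindex))
})

test_that("nested-event mode separates the older and younger signals", {
  # construction: within-pair copies identical, cross-pair strongly biased
  nw <- 10
  ret <- function(x) rep(x, nw)
  prof <- retention_profile(tibble::tibble(
    chrom = "c1", window = rep(1:nw, 4), n_genes = 100L,
    track = rep(1:4, each = nw),
    retention = c(ret(0.9), ret(0.9), ret(0.4), ret(0.4))
  ), M = 100)
  res <- pindex_recursive(prof, pairing = list(c(1, 2), c(3, 4)))
  expect_equal(res$alpha$status, "undefined")
  expect_equal(res$alpha$pindex, 0)
  expect_equal(res$beta$pindex, 1.0)
  # all four identical: both undefined
  prof_same <- retention_profile(tibble::tibble(
    chrom = "c1", window = rep(1:nw, 4), n_genes = 100L,
    track = rep(1:4, each = nw), retention = 0.7
  ), M = 100)
  res_same <- pindex_recursive(prof_same)
  expect_equal(res_same$alpha$status, "undefined")
  expect_equal(res_same$beta$status, "undefined")
  expect_error(pindex_recursive(prof, pairing = list(c(1, 2), c(2, 4))),
               "partition")
})

test_that("a two-round fixture yields beta above and alpha below threshold", {
  fx <- cached_fixture("two_round", scenario = "two_round",
                       n_chromosomes = 6, genes_per_chromosome = 1000,
                       seed = 31)
  masks <- split(fx$truth, fx$truth$ref_chrom) |>
    lapply(function(ch) {
      m <- matrix(FALSE, max(ch$ref_rank) + 1L, 4)
      for (k in 1:4) {
        sub <- ch[ch$subgenome == k, ]
        m[sub$ref_rank + 1L, k] <- !is.na(sub$qry_gene)
      }
      m
    })
  prof <- retention_from_masks(masks, M = 100)
  res <- pindex_recursive(prof, pairing = fx$pairing)
  expect_gt(res$beta$pindex, 0.3)
  expect_lt(res$alpha$pindex, 0.3)
  expect_gt(res$beta$pindex, res$alpha$pindex)
})

test_that("pairwise distance matrices are symmetric, zero-diagonal, grouped", {
  nw <- 12
  prof <- retention_profile(tibble::tibble(
    chrom = "c1", window = rep(1:nw, 3), n_genes = 100L,
    track = rep(1:3, each = nw),
    retention = c(rep(0.9, nw), rep(0.9, nw), rep(0.4, nw))
  ), M = 100)
  dm <- pairwise_matrix(prof)
  expect_true(isSymmetric(dm$matrix))
  expect_equal(diag(dm$matrix), setNames(rep(0, 3), 1:3))
  expect_equal(unname(dm$grouping[1]), unname(dm$grouping[2]))
  expect_false(unname(dm$grouping[1]) == unname(dm$grouping[3]))
  expect_error(pairwise_matrix(random_profile_case(3)$profile), "S >= 3")
  td <- tidy(dm)
  expect_equal(nrow(td), 3)
})

test_that("a planted 2+3 decaploid group structure is recovered", {
  fx <- cached_fixture("decaploid", scenario = "decaploid_grouped",
                       n_chromosomes = 6, genes_per_chromosome = 1000,
                       seed = 41)
  masks <- split(fx$truth, fx$truth$ref_chrom) |>
    lapply(function(ch) {
      m <- matrix(FALSE, max(ch$ref_rank) + 1L, 5)
      for (k in 1:5) {
        sub <- ch[ch$subgenome == k, ]
        m[sub$ref_rank + 1L, k] <- !is.na(sub$qry_gene)
      }
      m
    })
  prof <- retention_from_masks(masks, M = 100)
  dm <- pairwise_matrix(prof)
  g <- dm$grouping
  expect_equal(unname(g[1]), unname(g[2]))
  expect_equal(unname(g[3]), unname(g[4]))
  expect_equal(unname(g[4]), unname(g[5]))
  expect_false(unname(g[1]) == unname(g[3]))
  # within-group divergence is milder than between-group divergence
  expect_gt(dm$integrated_between,
            max(dm$integrated_within$integrated_pindex, na.rm = TRUE))
})
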