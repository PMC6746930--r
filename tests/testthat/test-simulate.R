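test_that("loss simulation honors its target and run-length law", {
  # no loss requested: mask untouched
  set.seed(1)
  m1 <- simulate_losses(1000, 1)
  expect_true(all(m1))
  expect_length(attr(m1, "deletion_runs"), 0)
  # p = 1: every deletion removes exactly one gene
  set.seed(2)
  m2 <- simulate_losses(2000, 0.7, run_length_p = 1)
  expect_true(all(attr(m2, "deletion_runs") == 1))
  expect_lte(mean(m2), 0.7)
  # realized retention lands just at-or-under the target, and the mean
  # deletion-event length matches the geometric mean 1/p
  runs <- c()
  for (seed in 1:20) {
    set.seed(seed)
    m <- simulate_losses(10000, 0.6, run_length_p = 0.5)
    expect_gte(mean(m), 0.595)
    expect_lte(mean(m), 0.6)
    runs <- c(runs, attr(m, "deletion_runs"))
  }
  expect_equal(mean(runs), 2, tolerance = 0.1)
  expect_error(simulate_losses(100, 0), "target_retention")
})

test_that("simulated distributions are reproducible from their config", {
  cfg <- simulation_config(n_chromosomes = 2, genes_per_chromosome = 500,
                           replicates = 5, seed = 42)
  s1 <- simulate_pindex(cfg)
  s2 <- simulate_pindex(cfg)
  expect_identical(s1$pindex, s2$pindex)
  expect_equal(nrow(s1), 5)
  expect_true(all(s1$pindex >= 0 & s1$pindex <= 1))
  # no loss at all: every replicate undefined and reported as 0
  cfg0 <- simulation_config(n_chromosomes = 2, genes_per_chromosome = 500,
                            target_retention = c(1, 1), replicates = 3)
  s0 <- simulate_pindex(cfg0)
  expect_true(all(s0$status == "undefined"))
  expect_true(all(s0$pindex == 0))
})

test_that("the balanced null shrinks as the number of windows grows", {
  means <- vapply(c(500, 1000, 2000), function(genes) {
    cfg <- simulation_config(n_chromosomes = 4,
                             genes_per_chromosome = genes,
                             replicates = 25, seed = 7)
    mean(simulate_pindex(cfg)$pindex)
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("balanced and strongly unbalanced genomes are classified apart", {
  bal <- simulate_pindex(simulation_config(
    n_chromosomes = 5, genes_per_chromosome = 1000,
    target_retention = c(0.6, 0.6), replicates = 40, seed = 11))
  unb <- simulate_pindex(simulation_config(
    n_chromosomes = 5, genes_per_chromosome = 1000,
    target_retention = c(0.75, 0.40), replicates = 40, seed = 11))
  correct <- sum(bal$pindex <= 0.3) + sum(unb$pindex > 0.3)
  expect_gte(correct / 80, 0.95)
})

test_that("simulation parameters are recovered from observed assignments", {
  # pass-through of observed per-track retention
  n <- 500
  set.seed(3)
  mA <- as.vector(simulate_losses(n, 0.52))
  mB <- as.vector(simulate_losses(n, 0.31))
  asg <- tibble::tibble(
    ref_chrom = "chr1", ref_rank = rep(0:(n - 1), each = 2),
    ref_gene = paste0("g", rep(0:(n - 1), each = 2)),
    track = rep(1:2, n),
    qry_gene = ifelse(c(rbind(mA, mB)), "x", NA_character_),
    block_id = "b"
  )
  cfg <- calibrate_from_observed(asg)
  expect_equal(cfg$target_retention, c(mean(mA), mean(mB)),
               tolerance = 1e-12)
  expect_equal(cfg$n_chromosomes, 1)
  expect_equal(cfg$genes_per_chromosome, n)
  # balanced variant pools the targets
  cfg_bal <- calibrate_from_observed(asg, balanced = TRUE)
  expect_equal(cfg_bal$target_retention,
               rep(mean(c(mean(mA), mean(mB))), 2))
  # method-of-moments on observed lost runs: lengths (1,2,3,2) -> p = 0.5
  lost_pattern <- rep(TRUE, 30)
  lost_pattern[c(2, 5:6, 10:12, 20:21)] <- FALSE
  asg_runs <- tibble::tibble(
    ref_chrom = "chr1", ref_rank = rep(0:29, each = 2),
    ref_gene = paste0("g", rep(0:29, each = 2)),
    track = rep(1:2, 30),
    qry_gene = ifelse(c(rbind(lost_pattern, rep(TRUE, 30))),
                      "x", NA_character_),
    block_id = "b"
  )
  expect_equal(calibrate_from_observed(asg_runs)$run_length_p, 0.5)
  # nothing lost: defaults to 0.5 with a warning
  asg_full <- asg_runs
  asg_full$qry_gene <- "x"
  expect_warning(cfg_full <- calibrate_from_observed(asg_full),
                 "no lost genes")
  expect_equal(cfg_full$run_length_p, 0.5)
})

test_that("the run-length parameter is recovered in the sparse regime", {
  # at high retention, deletion events rarely merge, so the moment
  # estimator tracks the generating p
  est <- vapply(1:20, function(seed) {
    set.seed(seed)
    m <- as.vector(simulate_losses(20000, 0.9, run_length_p = 0.4))
    r <- rle(!m)
    1 / mean(r$lengths[r$values])
  }, 0)
  expect_gte(mean(est), 0.33)
  expect_lte(mean(est), 0.47)
})
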