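#' Simulation configuration
#'
#' Bundles and validates the parameters of the post-polyploidy gene-loss
#' simulation. Gene loss is modeled as deletion events that remove runs of
#' consecutive (still-retained) genes whose lengths follow a geometric
#' distribution with success parameter `run_length_p` (mean run length
#' `1/run_length_p`; the default 0.5 gives mean runs of 2 genes), repeated
#' until each subgenome reaches its retention target.
#'
#' @param n_chromosomes Number of ancestor chromosomes (default 10).
#' @param genes_per_chromosome Genes per ancestor chromosome (default 2000).
#' @param S Number of subgenome copies (default 2).
#' @param target_retention Per-subgenome retained fraction, length `S` (a
#'   single value is recycled). Equal targets model balanced (auto-like)
#'   loss; distinct targets model unbalanced (allo-like) loss.
#' @param run_length_p Geometric run-length parameter in (0, 1\].
#' @param M,tau Windowing and flag parameters for the computed P-index.
#' @param replicates Number of simulation replicates.
#' @param seed Seed of the first replicate; replicate `j` uses
#'   `seed + j - 1`.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_chromosomes = 10,
                              genes_per_chromosome = 2000,
                              S = 2,
                              target_retention = c(0.6, 0.6),
                              run_length_p = 0.5,
                              M = 100, tau = 0.05,
                              replicates = 100, seed = 1) {
  if (length(target_retention) == 1) {
    target_retention <- rep(target_retention, S)
  }
  if (length(target_retention) != S) {
    abort("target_retention must have one value per subgenome")
  }
  if (any(target_retention <= 0 | target_retention > 1)) {
    abort("target_retention values must lie in (0, 1]")
  }
  if (run_length_p <= 0 || run_length_p > 1) {
    abort("run_length_p must lie in (0, 1]")
  }
  if (replicates < 1) abort("replicates must be >= 1")
  structure(
    list(n_chromosomes = n_chromosomes,
         genes_per_chromosome = genes_per_chromosome,
         S = S, target_retention = target_retention,
         run_length_p = run_length_p, M = M, tau = tau,
         replicates = as.integer(replicates), seed = as.integer(seed),
         rng_kind = "Mersenne-Twister"),
    class = "simulation_config"
  )
}

#' Simulate gene loss in geometric runs
#'
#' Deletes genes from a chromosome of `gene_count` genes in runs: each
#' deletion event starts at a uniformly random still-retained position,
#' draws a run length `L` from a geometric distribution on 1, 2, ...
#' (success parameter `run_length_p`), and removes the next `L`
#' still-retained genes in rank order (truncated at the chromosome end).
#' Events repeat until the retained fraction is at or below
#' `target_retention`; the final event may overshoot the target, so the
#' realized retention is within one run length of the target. Uses R's
#' current RNG stream (set a seed for reproducibility).
#'
#' @param gene_count Number of genes on the chromosome.
#' @param target_retention Target retained fraction in (0, 1\].
#' @param run_length_p Geometric success parameter in (0, 1\]; `1` makes
#'   every deletion remove exactly one gene.
#' @return A logical vector of length `gene_count` (`TRUE` = retained) with
#'   attribute `deletion_runs`: the realized length of every deletion event.
#' @examples
#' set.seed(1)
#' mask <- simulate_losses(1000, 0.6)
#' mean(mask)
#' mean(attr(mask, "deletion_runs")) # about 1 / run_length_p
#' @export
simulate_losses <- function(gene_count, target_retention,
                            run_length_p = 0.5) {
  if (gene_count < 1) abort("gene_count must be >= 1")
  if (target_retention <= 0 || target_retention > 1) {
    abort("target_retention must lie in (0, 1]")
  }
  if (run_length_p <= 0 || run_length_p > 1) {
    abort("run_length_p must lie in (0, 1]")
  }
  retained <- rep(TRUE, gene_count)
  n_ret <- gene_count
  target_n <- target_retention * gene_count
  runs <- integer(0)
  while (n_ret > target_n) {
    repeat {
      idx <- sample.int(gene_count, 1L)
      if (retained[idx]) break
    }
    L <- rgeom(1L, run_length_p) + 1L
    deleted <- 0L
    j <- idx
    while (deleted < L && j <= gene_count) {
      if (retained[j]) {
        retained[j] <- FALSE
        deleted <- deleted + 1L
        n_ret <- n_ret - 1L
      }
      j <- j + 1L
    }
    runs <- c(runs, deleted)
  }
  attr(retained, "deletion_runs") <- runs
  retained
}

#' Simulated P-index distribution
#'
#' Runs the full gene-loss experiment: per replicate, an intact ancestor of
#' `n_chromosomes x genes_per_chromosome` genes is duplicated into `S`
#' subgenome copies, each copy is fractionated with [simulate_losses()] to
#' its retention target, the copies are profiled against the intact ancestor
#' ([retention_from_masks()]) and the P-index is computed ([pindex_pair()]
#' for S = 2, [pindex_multi()] otherwise). Replicate `j` is seeded with
#' `seed + j - 1`, so the full distribution is reproducible from the config.
#'
#' @param config A `simulation_config`.
#' @return A tibble of class `simulated_distribution` with columns
#'   `replicate`, `seed`, `pindex`, `status`; attributes `config` and
#'   `summary` (mean, sd, min, max, 2.5%/97.5% quantiles; see [glance()]).
#' @examples
#' cfg <- simulation_config(n_chromosomes = 2, genes_per_chromosome = 500,
#'                          replicates = 5)
#' sim <- simulate_pindex(cfg)
#' glance(sim)
#' @export
simulate_pindex <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  reps <- config$replicates
  values <- numeric(reps)
  status <- character(reps)
  seeds <- config$seed + seq_len(reps) - 1L
  for (j in seq_len(reps)) {
    set.seed(seeds[j])
    masks <- replicate(config$n_chromosomes, {
      do.call(cbind, lapply(seq_len(config$S), function(k) {
        as.vector(simulate_losses(config$genes_per_chromosome,
                                  config$target_retention[k],
                                  config$run_length_p))
      }))
    }, simplify = FALSE)
    names(masks) <- paste0("chr", seq_len(config$n_chromosomes))
    prof <- retention_from_masks(masks, M = config$M)
    res <- if (config$S == 2) {
      pindex_pair(prof, tau = config$tau)
    } else {
      pindex_multi(prof, tau = config$tau)
    }
    values[j] <- res$pindex
    status[j] <- res$status
  }
  out <- tibble(replicate = seq_len(reps), seed = seeds,
                pindex = values, status = status)
  attr(out, "config") <- config
  attr(out, "summary") <- list(
    mean = mean(values), sd = if (reps > 1) sd(values) else NA_real_,
    min = min(values), max = max(values),
    q025 = unname(quantile(values, 0.025)),
    q975 = unname(quantile(values, 0.975))
  )
  class(out) <- c("simulated_distribution", class(out))
  out
}

#' @export
#' @method glance simulated_distribution
glance.simulated_distribution <- function(x, ...) {
  s <- attr(x, "summary")
  cfg <- attr(x, "config")
  tibble(
    replicates = nrow(x), mean = s$mean, sd = s$sd,
    min = s$min, max = s$max, q025 = s$q025, q975 = s$q975,
    n_undefined = sum(x$status == "undefined"),
    S = cfg$S,
    retention = paste(cfg$target_retention, collapse = "/"),
    run_length_p = cfg$run_length_p, seed = cfg$seed
  )
}

#' @export
print.simulated_distribution <- function(x, ...) {
  s <- attr(x, "summary")
  cat("<simulated P-index distribution>", nrow(x), "replicate(s); mean",
      format(s$mean, digits = 4), "| 95% of values in [",
      format(s$q025, digits = 3), ",", format(s$q975, digits = 3), "]\n")
  NextMethod()
}

#' @export
#' @method autoplot simulated_distribution
autoplot.simulated_distribution <- function(object, threshold = 0.3, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pindex)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60", color = "white") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::xlim(-0.02, 1.02) +
    ggplot2::labs(x = "simulated P-index", y = "replicates")
}

#' Calibrate a simulation from an observed assignment
#'
#' Reads the simulation parameters off an observed subgenome assignment:
#' per-track retention targets are the genome-wide retained fractions, and
#' the run-length parameter is fitted by method of moments on the observed
#' contiguous lost runs (`p = 1 / mean run length`). Independent deletion
#' events merge into longer observed runs when fractionation is heavy, so
#' the fitted `p` is a lower bound in that regime.
#'
#' @param assignment A `subgenome_assignment`.
#' @param geometry Optional `c(n_chromosomes, genes_per_chromosome)`;
#'   defaults to the assignment's chromosome count and mean length.
#' @param balanced If `TRUE`, set every retention target to the pooled mean
#'   (the balanced null used for comparison).
#' @param ... Passed to [simulation_config()] (e.g. `replicates`, `seed`).
#' @return A `simulation_config`.
#' @export
calibrate_from_observed <- function(assignment, geometry = NULL,
                                    balanced = FALSE, ...) {
  df <- as_tibble(assignment)
  if (nrow(df) == 0) abort("empty subgenome assignment")
  tracks <- sort(unique(df$track))
  r_k <- vapply(tracks, function(t) {
    sub <- df[df$track == t, ]
    mean(!is.na(sub$qry_gene))
  }, 0)
  run_lengths <- unlist(lapply(tracks, function(t) {
    sub <- df[df$track == t, ]
    unlist(lapply(split(sub, sub$ref_chrom), function(ch) {
      lost <- is.na(ch$qry_gene[order(ch$ref_rank)])
      r <- rle(lost)
      r$lengths[r$values]
    }))
  }))
  if (length(run_lengths) == 0) {
    warn("no lost genes observed; run_length_p defaults to 0.5")
    p <- 0.5
  } else {
    p <- 1 / mean(run_lengths)
  }
  if (balanced) r_k <- rep(mean(r_k), length(tracks))
  geometry <- geometry %||% c(
    n_distinct(df$ref_chrom),
    round(nrow(df) / n_distinct(df$ref_chrom) / length(tracks))
  )
  simulation_config(
    n_chromosomes = geometry[1],
    genes_per_chromosome = geometry[2],
    S = length(tracks),
    target_retention = r_k,
    run_length_p = p,
    ...
  )
}

#' Write a simulated distribution and its config echo
#'
#' Writes the replicate table as TSV and, alongside it, a key/value config
#' echo (`<path>.config`) sufficient to reproduce the run exactly.
#'
#' @param sim A `simulated_distribution`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_simulated_distribution <- function(sim, path) {
  readr::write_tsv(as_tibble(sim), path, col_names = TRUE)
  cfg <- attr(sim, "config")
  s <- attr(sim, "summary")
  lines <- c(
    paste0("n_chromosomes: ", cfg$n_chromosomes),
    paste0("genes_per_chromosome: ", cfg$genes_per_chromosome),
    paste0("S: ", cfg$S),
    paste0("target_retention: ",
           paste(cfg$target_retention, collapse = ",")),
    paste0("run_length_p: ", cfg$run_length_p),
    paste0("M: ", cfg$M),
    paste0("tau: ", cfg$tau),
    paste0("replicates: ", cfg$replicates),
    paste0("seed: ", cfg$seed),
    paste0("rng_kind: ", cfg$rng_kind),
    paste0("mean_pindex: ", sprintf("%.17g", s$mean))
  )
  writeLines(lines, paste0(path, ".config"))
  invisible(path)
}
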