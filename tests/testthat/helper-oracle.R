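# Independent oracle: the refined statistic computed with plain loops,
# straight from raw per-window retention rates. Deliberately shares no code
# with the package implementation.
#
# chroms: list of lists, each with numeric vectors A and B (same length).
naive_pindex <- function(chroms, tau = 0.05) {
  terms <- c()
  n_inf <- c()
  for (ch in chroms) {
    A <- ch$A
    B <- ch$B
    s <- 0
    ninf <- 0
    for (i in seq_along(A)) {
      tot <- A[i] + B[i]
      d <- if (tot == 0) 0 else abs(A[i] - B[i]) / (0.5 * tot)
      if (d >= tau) {
        ninf <- ninf + 1
        if (A[i] > B[i]) s <- s + 1
        if (A[i] < B[i]) s <- s - 1
      }
    }
    if (ninf > 0) {
      terms <- c(terms, abs(s) / ninf)
      n_inf <- c(n_inf, ninf)
    }
  }
  if (length(terms) == 0) return(list(pindex = 0, status = "undefined"))
  w <- n_inf / sum(n_inf)
  list(pindex = sum(w * terms), status = "ok")
}

# random retention profile in package form + oracle form
random_profile_case <- function(seed, S = 2) {
  set.seed(seed)
  n_chrom <- sample(1:20, 1)
  rows <- list()
  chroms <- list()
  for (c_i in seq_len(n_chrom)) {
    nw <- sample(5:50, 1)
    r <- matrix(runif(nw * S), nw, S)
    # sprinkle degenerate windows (all-zero retention)
    zero <- runif(nw) < 0.05
    r[zero, ] <- 0
    rows[[c_i]] <- tibble::tibble(
      chrom = paste0("c", c_i),
      window = rep(seq_len(nw), S),
      n_genes = 100L,
      track = rep(seq_len(S), each = nw),
      retention = as.vector(r)
    )
    chroms[[c_i]] <- list(A = r[, 1], B = r[, 2])
  }
  list(
    profile = retention_profile(dplyr::bind_rows(rows), M = 100),
    chroms = chroms
  )
}

swap_tracks_pair <- function(profile) {
  df <- tibble::as_tibble(profile)
  df$track <- 3L - df$track
  retention_profile(df, M = attr(profile, "M"))
}
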