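#' Windowed gene-retention profile of a subgenome assignment
#'
#' Divides each reference chromosome into consecutive non-overlapping windows
#' of `M` reference genes (gene ranks, not base pairs) and computes, for each
#' subgenome track, the fraction of the window's reference genes with a
#' retained collinear copy. The trailing partial window is kept only when it
#' holds at least `min_last_window * M` genes, and its retention is computed
#' over its actual gene count; chromosomes too short for even one such window
#' are excluded with a warning.
#'
#' @param assignment A `subgenome_assignment` from [partition_subgenomes()]
#'   (or any data frame with columns `ref_chrom`, `ref_rank`, `track`,
#'   `qry_gene` where `NA` marks a lost gene).
#' @param M Window size in reference genes (default 100).
#' @param min_last_window Minimum size of the trailing window as a fraction
#'   of `M` (default 0.5).
#' @return A tibble of class `retention_profile` with columns `chrom`,
#'   `window` (1-based), `n_genes`, `track`, `retained`, `retention`, and
#'   attributes `M` and `S`.
#' @export
compute_retention <- function(assignment, M = 100, min_last_window = 0.5) {
  if (M < 10) abort("window size M must be >= 10")
  df <- as_tibble(assignment)
  if (nrow(df) == 0) abort("empty subgenome assignment")
  tracks <- sort(unique(df$track))
  chroms <- unique(df$ref_chrom)
  masks <- lapply(chroms, function(cc) {
    sub <- df[df$ref_chrom == cc, ]
    n <- max(sub$ref_rank) + 1L
    m <- matrix(FALSE, nrow = n, ncol = length(tracks))
    for (ti in seq_along(tracks)) {
      r <- sub$ref_rank[sub$track == tracks[ti] & !is.na(sub$qry_gene)]
      m[r + 1L, ti] <- TRUE
    }
    m
  })
  names(masks) <- chroms
  retention_from_masks(masks, M = M, min_last_window = min_last_window,
                       track_ids = tracks)
}

#' Build a retention profile directly from retention masks
#'
#' Lower-level constructor used by [compute_retention()], the gene-loss
#' simulator and the fixture generator: takes per-chromosome logical matrices
#' (reference genes in rank order x subgenome tracks, `TRUE` = retained) and
#' windows them.
#'
#' @param masks Named list of logical matrices, one per reference
#'   chromosome; rows are reference gene ranks, columns subgenome tracks.
#' @param M Window size in reference genes.
#' @param min_last_window Minimum trailing-window size as a fraction of `M`.
#' @param track_ids Optional integer track labels (default `1:S`).
#' @return A `retention_profile` tibble (see [compute_retention()]).
#' @export
retention_from_masks <- function(masks, M = 100, min_last_window = 0.5,
                                 track_ids = NULL) {
  if (M < 10) abort("window size M must be >= 10")
  S <- ncol(masks[[1]])
  track_ids <- track_ids %||% seq_len(S)
  min_genes <- min_last_window * M
  dropped <- character()
  parts <- vector("list", length(masks))
  for (ci in seq_along(masks)) {
    m <- masks[[ci]]
    n <- nrow(m)
    win <- (seq_len(n) - 1L) %/% M + 1L
    sizes <- tabulate(win)
    keep_w <- which(sizes >= min_genes)
    if (length(keep_w) == 0) {
      dropped <- c(dropped, names(masks)[ci])
      next
    }
    counts <- rowsum(m + 0L, win)[keep_w, , drop = FALSE]
    parts[[ci]] <- tibble(
      chrom = names(masks)[ci],
      window = rep(keep_w, each = S),
      n_genes = rep(sizes[keep_w], each = S),
      track = rep(track_ids, times = length(keep_w)),
      retained = as.integer(t(counts)),
      retention = as.integer(t(counts)) / rep(sizes[keep_w], each = S)
    )
  }
  if (length(dropped) > 0) {
    warn(paste0("chromosome(s) shorter than ", min_genes,
                " genes excluded: ", paste(dropped, collapse = ", ")))
  }
  out <- list_rbind(parts[!vapply(parts, is.null, TRUE)])
  if (is.null(out) || nrow(out) == 0) abort("no chromosome long enough to window")
  new_retention_profile(out, M = M, S = length(track_ids))
}

#' Construct a retention profile from a plain table
#'
#' Validates and classes a data frame with columns `chrom`, `window`,
#' `n_genes`, `track`, `retention` (and optionally `retained`) as a
#' `retention_profile`.
#'
#' @param df The table of windowed retention rates.
#' @param M Window size the profile was built with.
#' @return A `retention_profile` tibble.
#' @export
retention_profile <- function(df, M = 100) {
  df <- as_tibble(df)
  required <- c("chrom", "window", "n_genes", "track", "retention")
  if (!all(required %in% names(df))) {
    abort(paste0("retention profile needs columns: ",
                 paste(required, collapse = ", ")))
  }
  if (any(df$retention < 0 | df$retention > 1)) {
    abort("retention rates must lie in [0, 1]")
  }
  if (!("retained" %in% names(df))) {
    df$retained <- as.integer(round(df$retention * df$n_genes))
  }
  new_retention_profile(df, M = M, S = n_distinct(df$track))
}

new_retention_profile <- function(df, M, S) {
  df <- as_tibble(df)
  attr(df, "M") <- M
  attr(df, "S") <- S
  class(df) <- c("retention_profile", class(df))
  df
}

#' @export
print.retention_profile <- function(x, ...) {
  cat("<retention profile>", n_distinct(x$chrom), "chromosome(s),",
      attr(x, "S"), "subgenome track(s), window size M =",
      attr(x, "M"), "\n")
  NextMethod()
}

#' Per-window informativeness flags
#'
#' Computes the relative retention-difference level `d` of every window and
#' flags windows as informative (`delta = 1`) when `d >= tau`. For two
#' subgenomes `d = |A - B| / (0.5 (A + B))`; windows with both copies absent
#' (`A + B = 0`) are defined as uninformative (`d = 0`). With more than two
#' subgenomes, `d` averages the absolute pairwise relative differences over
#' `pair_set`, divided by the number of pairs (`pair_norm = "pairs"`, the
#' default, which reduces exactly to the two-subgenome definition) or by the
#' number of subgenomes `S` (`pair_norm = "S"`, the literal published form).
#'
#' @param profile A `retention_profile`.
#' @param tau Informativeness threshold on `d` (default 0.05); must lie in
#'   (0, 1).
#' @param pair_set Two-column matrix (or list of length-2 vectors) of track
#'   index pairs to compare; defaults to all pairs `k < j`.
#' @param pair_norm `"pairs"` or `"S"`.
#' @return A tibble of class `window_flags` with columns `chrom`, `window`,
#'   `d`, `delta`, and attributes `tau`, `pair_set`, `pair_norm`.
#' @examples
#' prof <- retention_profile(tibble::tibble(
#'   chrom = "c1", window = 1:2, n_genes = 10,
#'   track = rep(1:2, each = 2), retention = c(1.0, 0.9, 0.5, 0.9)
#' ), M = 10)
#' compute_flags(prof) # window 1: d = 0.667, informative; window 2: d = 0
#' @export
compute_flags <- function(profile, tau = 0.05, pair_set = NULL,
                          pair_norm = c("pairs", "S")) {
  pair_norm <- match.arg(pair_norm)
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1) {
    abort("tau must be a single number in (0, 1)")
  }
  tracks <- sort(unique(profile$track))
  S <- length(tracks)
  pair_set <- normalize_pair_set(pair_set, tracks)
  wide <- retention_wide(profile)
  d <- rep(0, nrow(wide))
  for (p in seq_len(nrow(pair_set))) {
    A <- wide[[track_col(pair_set[p, 1])]]
    B <- wide[[track_col(pair_set[p, 2])]]
    s <- A + B
    rel <- ifelse(s == 0, 0, abs(A - B) / (0.5 * s))
    d <- d + rel
  }
  d <- d / if (pair_norm == "pairs") nrow(pair_set) else S
  out <- tibble(
    chrom = wide$chrom,
    window = wide$window,
    d = d,
    delta = as.integer(d >= tau)
  )
  attr(out, "tau") <- tau
  attr(out, "pair_set") <- pair_set
  attr(out, "pair_norm") <- pair_norm
  class(out) <- c("window_flags", class(out))
  out
}

normalize_pair_set <- function(pair_set, tracks) {
  if (is.null(pair_set)) {
    if (length(tracks) < 2) abort("need at least 2 subgenome tracks")
    cmb <- utils::combn(tracks, 2)
    pair_set <- t(cmb)
  } else if (is.list(pair_set)) {
    pair_set <- do.call(rbind, lapply(pair_set, as.integer))
  } else {
    pair_set <- matrix(as.integer(pair_set), ncol = 2)
  }
  if (nrow(pair_set) == 0) abort("pair_set must be non-empty")
  if (!all(pair_set %in% tracks)) {
    abort("pair_set refers to unknown subgenome track indices")
  }
  pair_set
}

track_col <- function(k) paste0("t", k)

retention_wide <- function(profile) {
  as_tibble(profile) |>
    select("chrom", "window", "n_genes", "track", "retention") |>
    mutate(track = track_col(.data$track)) |>
    pivot_wider(names_from = "track", values_from = "retention") |>
    arrange(.data$chrom, .data$window)
}

#' @export
#' @method autoplot retention_profile
autoplot.retention_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$window, y = .data$retention,
                               color = factor(.data$track))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "window (reference gene rank / M)",
                  y = "gene retention rate", color = "subgenome\ntrack")
}

#' Write a retention profile (with flags) as TSV
#'
#' @param profile A `retention_profile`.
#' @param path Output path.
#' @param flags Optional `window_flags` to append as `d` and `delta` columns.
#' @return `path`, invisibly.
#' @export
write_retention_profile <- function(profile, path, flags = NULL) {
  wide <- retention_wide(profile)
  names(wide) <- sub("^t", "A_", names(wide))
  if (!is.null(flags)) {
    wide <- left_join(wide, as_tibble(flags), by = c("chrom", "window"))
  }
  readr::write_tsv(wide, path, col_names = TRUE)
  invisible(path)
}
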