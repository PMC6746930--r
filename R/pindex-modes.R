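#' P-index from triple homoeology without an external reference
#'
#' For genomes whose own structure preserves a whole-genome triplication
#' (three homoeologous copies of each ancestral region), one copy of each
#' triple serves as the internal reference and the other two are compared
#' against it. Windows are built on the internal reference copy's retained
#' genes only: ancestral positions lost from the reference copy are skipped
#' entirely, which amounts to a random subsample of loci when losses are
#' random. The two compared copies then form a two-track profile scored with
#' [pindex_pair()].
#'
#' @param triples A data frame with one row per ancestral gene position:
#'   columns `triple_id` (region identifier, treated as a chromosome),
#'   `pos` (ordering within the region) and three logical presence columns
#'   named in `regions` (`TRUE` = gene retained in that copy).
#' @param regions Names of the three presence columns (default
#'   `c("r1", "r2", "r3")`).
#' @param reference Which of the three copies is the internal reference
#'   (index into `regions`, default 1). Ignored when `rotate = TRUE`.
#' @param rotate If `TRUE`, compute the index for all three choices of
#'   reference copy and report each with their mean.
#' @param M,tau,min_last_window Windowing and flag parameters.
#' @return With `rotate = FALSE`, a `pindex_result` (mode `"selfref"`).
#'   With `rotate = TRUE`, an object of class `pindex_rotation`: a list with
#'   `results` (one `pindex_result` per reference choice), `summary` (a
#'   tibble of reference choice, P-index, status) and `mean_pindex`.
#' @export
pindex_selfref <- function(triples, regions = c("r1", "r2", "r3"),
                           reference = 1, rotate = FALSE,
                           M = 100, tau = 0.05, min_last_window = 0.5) {
  triples <- as_tibble(triples)
  if (length(regions) < 3) {
    abort("a homoeologous triple needs 3 region columns")
  }
  regions <- regions[1:3]
  if (!all(c("triple_id", "pos", regions) %in% names(triples))) {
    abort(paste0("triples must have columns triple_id, pos, ",
                 paste(regions, collapse = ", ")))
  }
  one <- function(ref_idx) {
    cmp <- regions[-ref_idx]
    kept <- triples |>
      filter(.data[[regions[ref_idx]]]) |>
      arrange(.data$triple_id, .data$pos)
    if (nrow(kept) == 0) abort("reference copy retains no genes")
    masks <- lapply(split(kept, kept$triple_id), function(k) {
      cbind(k[[cmp[1]]], k[[cmp[2]]])
    })
    prof <- retention_from_masks(masks, M = M,
                                 min_last_window = min_last_window)
    res <- pindex_pair(prof, tau = tau)
    res$mode <- "selfref"
    res$params$reference_region <- regions[ref_idx]
    res
  }
  if (!rotate) return(one(reference))
  results <- lapply(1:3, one)
  summary <- tibble(
    reference = regions,
    pindex = map_dbl(results, "pindex"),
    status = map_chr(results, "status")
  )
  structure(
    list(results = results, summary = summary,
         mean_pindex = mean(summary$pindex)),
    class = "pindex_rotation"
  )
}

#' @export
print.pindex_rotation <- function(x, ...) {
  cat("<P-index, self-reference rotation>\n")
  print(x$summary)
  cat("mean P-index:", format(x$mean_pindex, digits = 4), "\n")
  invisible(x)
}

#' P-indices of two nested polyploidy events
#'
#' For a genome shaped by two rounds of whole-genome duplication there are
#' four homoeologous copies of each reference region; the caller supplies
#' the event pairing, i.e. which two copies descend from each product of the
#' older (beta) event. The younger (alpha) event's index is computed within
#' each pair (terms combined per chromosome as an informative-window-weighted
#' mean before global weighting); the older event's index compares the four
#' cross-pair combinations with the multi-subgenome formula.
#'
#' @param profile A `retention_profile` with exactly 4 tracks.
#' @param pairing List of two length-2 vectors partitioning the 4 track
#'   indices into the two products of the older event, e.g.
#'   `list(c(1, 2), c(3, 4))`.
#' @param flags Optional `window_flags` for the beta (cross-pair)
#'   computation; alpha flags are always computed per within-event pair.
#' @param tau,weight_scheme See [pindex_pair()].
#' @return A list of class `pindex_recursive` with elements `alpha` and
#'   `beta`, each a `pindex_result`.
#' @export
pindex_recursive <- function(profile, pairing = list(c(1, 2), c(3, 4)),
                             flags = NULL, tau = 0.05,
                             weight_scheme = c("informative", "raw")) {
  weight_scheme <- match.arg(weight_scheme)
  tracks <- sort(unique(profile$track))
  if (length(tracks) != 4) {
    abort("recursive-event mode needs exactly 4 subgenome tracks")
  }
  flat <- sort(unlist(pairing))
  if (length(pairing) != 2 || !identical(as.integer(flat),
                                         as.integer(tracks))) {
    abort("pairing must partition the 4 tracks into 2 pairs")
  }
  # alpha: within-pair comparisons pooled per chromosome
  pair_terms <- lapply(pairing, function(pr) {
    sub <- as_tibble(profile) |> filter(.data$track %in% pr)
    sub <- new_retention_profile(sub, M = attr(profile, "M"), S = 2)
    fl <- compute_flags(sub, tau = tau)
    wide <- retention_wide(sub) |>
      inner_join(as_tibble(fl), by = c("chrom", "window"))
    A <- wide[[track_col(pr[1])]]
    B <- wide[[track_col(pr[2])]]
    wide |>
      mutate(signed = sign(A - B) * .data$delta) |>
      group_by(.data$chrom) |>
      summarise(n_windows = n(),
                n_informative = sum(.data$delta),
                signed_sum = abs(sum(.data$signed)),
                .groups = "drop")
  })
  combined <- bind_rows(pair_terms) |>
    group_by(.data$chrom) |>
    summarise(
      n_windows = sum(.data$n_windows),
      n_informative = sum(.data$n_informative),
      signed_total = sum(.data$signed_sum),
      .groups = "drop"
    ) |>
    mutate(term = ifelse(.data$n_informative > 0,
                         .data$signed_total / .data$n_informative,
                         NA_real_)) |>
    select("chrom", "n_windows", "n_informative", "term")
  alpha <- finalize_pindex(
    combined, weight_scheme, mode = "recursive_alpha",
    params = list(M = attr(profile, "M"), tau = tau,
                  weight_scheme = weight_scheme,
                  pairing = paste(map_chr(pairing, paste, collapse = "+"),
                                  collapse = " | "))
  )
  cross <- as.matrix(expand.grid(pairing[[1]], pairing[[2]]))
  beta <- pindex_multi(profile, flags = flags, pair_set = cross,
                       weight_scheme = weight_scheme, tau = tau)
  beta$mode <- "recursive_beta"
  structure(list(alpha = alpha, beta = beta), class = "pindex_recursive")
}

#' @export
print.pindex_recursive <- function(x, ...) {
  cat("<P-index, two nested events>\n")
  cat("  alpha (younger):", format(x$alpha$pindex, digits = 4),
      if (x$alpha$status != "ok") paste0("(", x$alpha$status, ")") else "",
      "\n")
  cat("  beta  (older):  ", format(x$beta$pindex, digits = 4),
      if (x$beta$status != "ok") paste0("(", x$beta$status, ")") else "",
      "\n")
  invisible(x)
}

#' Pairwise subgenome distance matrix with grouping
#'
#' Treats the pairwise P-index as a distance between subgenome tracks:
#' every pair of tracks is scored with [pindex_pair()] (with pair-specific
#' window flags), giving a symmetric S x S matrix with zero diagonal. Tracks
#' are then grouped by average-linkage agglomeration, cutting at the number
#' of groups (2 to S-1) that maximizes the difference between the mean
#' between-group and mean within-group pairwise values. Integrated indices
#' are the group means of pairwise entries.
#'
#' @param profile A `retention_profile` with S >= 3 tracks.
#' @param tau,weight_scheme See [pindex_pair()].
#' @return An object of class `subgenome_distance`: list with `matrix`
#'   (S x S), `grouping` (named integer vector track -> group),
#'   `integrated_within` (tibble of per-group mean pairwise P-index),
#'   `integrated_between` (pooled mean over between-group pairs).
#' @export
pairwise_matrix <- function(profile, tau = 0.05,
                            weight_scheme = c("informative", "raw")) {
  weight_scheme <- match.arg(weight_scheme)
  tracks <- sort(unique(profile$track))
  S <- length(tracks)
  if (S < 3) abort("pairwise_matrix() needs S >= 3 tracks")
  mat <- matrix(0, S, S, dimnames = list(tracks, tracks))
  for (a in seq_len(S - 1)) {
    for (b in (a + 1):S) {
      sub <- as_tibble(profile) |>
        filter(.data$track %in% c(tracks[a], tracks[b]))
      sub <- new_retention_profile(sub, M = attr(profile, "M"), S = 2)
      res <- pindex_pair(sub, tau = tau, weight_scheme = weight_scheme)
      mat[a, b] <- mat[b, a] <- res$pindex
    }
  }
  hc <- hclust(as.dist(mat), method = "average")
  best <- NULL
  best_score <- -Inf
  for (k in 2:(S - 1)) {
    grp <- cutree(hc, k = k)
    same <- outer(grp, grp, "==")
    ut <- upper.tri(mat)
    within_vals <- mat[ut & same]
    between_vals <- mat[ut & !same]
    if (length(within_vals) == 0 || length(between_vals) == 0) next
    score <- mean(between_vals) - mean(within_vals)
    if (score > best_score) {
      best_score <- score
      best <- grp
    }
  }
  grp <- best
  ut <- upper.tri(mat)
  same <- outer(grp, grp, "==")
  within <- tibble(
    group = sort(unique(grp)),
    integrated_pindex = vapply(sort(unique(grp)), function(g) {
      sel <- ut & same & outer(grp == g, grp == g, "&")
      if (any(sel)) mean(mat[sel]) else NA_real_
    }, 0)
  )
  structure(
    list(matrix = mat, grouping = grp,
         integrated_within = within,
         integrated_between = mean(mat[ut & !same])),
    class = "subgenome_distance"
  )
}

#' @export
print.subgenome_distance <- function(x, ...) {
  cat("<subgenome distance matrix> (pairwise P-indices)\n")
  print(round(x$matrix, 3))
  cat("grouping:", paste(paste0(names(x$grouping), ":", x$grouping),
                         collapse = " "), "\n")
  cat("integrated between-group P-index:",
      format(x$integrated_between, digits = 3), "\n")
  invisible(x)
}

#' @export
#' @method tidy subgenome_distance
tidy.subgenome_distance <- function(x, ...) {
  S <- nrow(x$matrix)
  idx <- which(upper.tri(x$matrix), arr.ind = TRUE)
  tibble(
    track1 = rownames(x$matrix)[idx[, 1]],
    track2 = colnames(x$matrix)[idx[, 2]],
    pindex = x$matrix[idx],
    same_group = x$grouping[idx[, 1]] == x$grouping[idx[, 2]]
  )
}

#' @export
#' @method autoplot subgenome_distance
autoplot.subgenome_distance <- function(object, ...) {
  df <- as.data.frame(as.table(object$matrix))
  names(df) <- c("track1", "track2", "pindex")
  ggplot2::ggplot(df, ggplot2::aes(.data$track1, .data$track2,
                                   fill = .data$pindex)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "subgenome track", y = "subgenome track",
                  fill = "pairwise\nP-index")
}
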