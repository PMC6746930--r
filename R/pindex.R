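#' P-index for a pair of subgenomes
#'
#' Computes the polyploidy index from a two-track retention profile. For each
#' reference chromosome the per-chromosome term is
#' `T_c = | sum_i sign(A_i - B_i) * delta_i | / n_c`, where the sum runs over
#' the chromosome's windows, `delta_i` flags informative windows (see
#' [compute_flags()]) and `n_c` is the number of informative windows.
#' Chromosomes with no informative window are excluded. The global statistic
#' is the weighted mean `sum_c W_c T_c` with weights proportional to the
#' informative window count (`weight_scheme = "informative"`, the default)
#' or to the raw window count (`weight_scheme = "raw"`); either way the
#' weights sum to 1 over included chromosomes, so the statistic lies in
#' \[0, 1\]: near 0 when gene loss is balanced between subgenomes, near 1
#' when one subgenome consistently lost more.
#'
#' If no chromosome has an informative window the result has status
#' `"undefined"` and a P-index of 0 (flagged, never silent).
#'
#' @param profile A `retention_profile` with exactly 2 tracks.
#' @param flags `window_flags` computed from the same profile; defaults to
#'   [compute_flags()] with `tau`.
#' @param weight_scheme `"informative"` or `"raw"`.
#' @param tau Threshold used when `flags` is not supplied.
#' @return A `pindex_result` object: fields `pindex`, `status`, `mode`,
#'   `chromosomes` (per-chromosome terms and weights), `params`.
#' @examples
#' prof <- retention_profile(tibble::tibble(
#'   chrom = "c1", window = rep(1:4, 2), n_genes = 100,
#'   track = rep(1:2, each = 4),
#'   retention = c(1.0, 0.9, 0.8, 0.7, 0.5, 0.9, 0.4, 0.35)
#' ), M = 100)
#' pindex_pair(prof) # three informative windows, all favoring track 1
#' @export
pindex_pair <- function(profile, flags = NULL,
                        weight_scheme = c("informative", "raw"),
                        tau = 0.05) {
  weight_scheme <- match.arg(weight_scheme)
  tracks <- sort(unique(profile$track))
  if (length(tracks) != 2) {
    abort("pindex_pair() needs exactly 2 subgenome tracks; use pindex_multi() for S > 2")
  }
  flags <- flags %||% compute_flags(profile, tau = tau)
  wide <- retention_wide(profile) |>
    inner_join(as_tibble(flags), by = c("chrom", "window"))
  A <- wide[[track_col(tracks[1])]]
  B <- wide[[track_col(tracks[2])]]
  per <- wide |>
    mutate(signed = sign(A - B) * .data$delta) |>
    group_by(.data$chrom) |>
    summarise(
      n_windows = n(),
      n_informative = sum(.data$delta),
      term = if (sum(.data$delta) > 0) {
        abs(sum(.data$signed)) / sum(.data$delta)
      } else NA_real_,
      .groups = "drop"
    )
  finalize_pindex(per, weight_scheme, mode = "pair",
                  params = list(
                    M = attr(profile, "M"), tau = attr(flags, "tau"),
                    weight_scheme = weight_scheme,
                    tracks = tracks
                  ))
}

#' P-index for S subgenomes
#'
#' Generalizes [pindex_pair()] to profiles with more than two subgenome
#' tracks: the per-chromosome numerator sums `sign(A_ki - A_ji) * delta_i`
#' over all compared track pairs and windows, and is normalized so the term
#' stays in \[0, 1\]. With `denominator_scheme = "informative_pairs"` (the
#' default) the divisor is `n_c * |pairs|`; `"printed"` uses the literal
#' published form `N_c * |pairs| - delta(N_c)` (the count of uninformative
#' windows subtracted once, not once per pair), which over-normalizes
#' slightly for S > 2 and is kept for fidelity comparisons. With S = 2 and
#' the full pair set the default scheme is identical to [pindex_pair()].
#'
#' @param profile A `retention_profile` with S >= 2 tracks.
#' @param flags Optional `window_flags` for the same `pair_set`.
#' @param pair_set Track pairs to compare (default all `k < j`).
#' @param denominator_scheme `"informative_pairs"` or `"printed"`.
#' @param weight_scheme `"informative"` or `"raw"` (see [pindex_pair()]).
#' @param tau Threshold used when `flags` is not supplied.
#' @param pair_norm Passed to [compute_flags()] when `flags` is not supplied.
#' @return A `pindex_result` object.
#' @export
pindex_multi <- function(profile, flags = NULL, pair_set = NULL,
                         denominator_scheme = c("informative_pairs", "printed"),
                         weight_scheme = c("informative", "raw"),
                         tau = 0.05, pair_norm = c("pairs", "S")) {
  denominator_scheme <- match.arg(denominator_scheme)
  weight_scheme <- match.arg(weight_scheme)
  pair_norm <- match.arg(pair_norm)
  tracks <- sort(unique(profile$track))
  if (length(tracks) < 2) abort("need at least 2 subgenome tracks")
  pair_set <- normalize_pair_set(pair_set, tracks)
  flags <- flags %||% compute_flags(profile, tau = tau, pair_set = pair_set,
                                    pair_norm = pair_norm)
  wide <- retention_wide(profile) |>
    inner_join(as_tibble(flags), by = c("chrom", "window"))
  signed <- rep(0, nrow(wide))
  for (p in seq_len(nrow(pair_set))) {
    A <- wide[[track_col(pair_set[p, 1])]]
    B <- wide[[track_col(pair_set[p, 2])]]
    signed <- signed + sign(A - B) * wide$delta
  }
  n_pairs <- nrow(pair_set)
  per <- wide |>
    mutate(signed = signed) |>
    group_by(.data$chrom) |>
    summarise(
      n_windows = n(),
      n_informative = sum(.data$delta),
      numerator = abs(sum(.data$signed)),
      .groups = "drop"
    ) |>
    mutate(
      denom = if (denominator_scheme == "informative_pairs") {
        .data$n_informative * n_pairs
      } else {
        .data$n_windows * n_pairs -
          (.data$n_windows - .data$n_informative)
      },
      term = ifelse(.data$n_informative > 0,
                    .data$numerator / .data$denom, NA_real_)
    ) |>
    select("chrom", "n_windows", "n_informative", "term")
  finalize_pindex(per, weight_scheme, mode = "multi",
                  params = list(
                    M = attr(profile, "M"), tau = attr(flags, "tau"),
                    weight_scheme = weight_scheme,
                    denominator_scheme = denominator_scheme,
                    n_pairs = n_pairs,
                    pair_set = paste(pair_set[, 1], pair_set[, 2],
                                     sep = "-", collapse = ";")
                  ))
}

finalize_pindex <- function(per, weight_scheme, mode, params) {
  incl <- per |> filter(.data$n_informative > 0)
  if (nrow(incl) == 0) {
    per$weight <- 0
    per$term[is.na(per$term)] <- 0
    return(new_pindex_result(0, "undefined", mode, per, params))
  }
  w <- if (weight_scheme == "informative") {
    incl$n_informative / sum(incl$n_informative)
  } else {
    incl$n_windows / sum(incl$n_windows)
  }
  incl$weight <- w
  p <- sum(w * incl$term)
  new_pindex_result(p, "ok", mode, incl, params)
}

new_pindex_result <- function(pindex, status, mode, chromosomes, params) {
  structure(
    list(pindex = pindex, status = status, mode = mode,
         chromosomes = as_tibble(chromosomes), params = params),
    class = "pindex_result"
  )
}

#' @export
print.pindex_result <- function(x, ...) {
  cat("<P-index result>\n")
  cat("  mode:   ", x$mode, "\n")
  cat("  P-index:", format(x$pindex, digits = 4),
      if (x$status != "ok") paste0("(status: ", x$status, ")") else "", "\n")
  cat("  chromosomes included:", nrow(x$chromosomes), "\n")
  invisible(x)
}

#' @export
#' @method tidy pindex_result
tidy.pindex_result <- function(x, ...) {
  x$chromosomes
}

#' @export
#' @method glance pindex_result
glance.pindex_result <- function(x, ...) {
  tibble(
    pindex = x$pindex,
    status = x$status,
    mode = x$mode,
    n_chromosomes = nrow(x$chromosomes),
    n_windows = sum(x$chromosomes$n_windows),
    n_informative = sum(x$chromosomes$n_informative),
    M = x$params$M %||% NA_real_,
    tau = x$params$tau %||% NA_real_
  )
}

#' @export
#' @method autoplot pindex_result
autoplot.pindex_result <- function(object, ...) {
  ch <- object$chromosomes
  ggplot2::ggplot(ch, ggplot2::aes(x = .data$chrom, y = .data$term,
                                   size = .data$weight)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$pindex, linetype = "dashed") +
    ggplot2::labs(x = "reference chromosome",
                  y = "per-chromosome term",
                  size = "weight",
                  title = paste0("P-index = ",
                                 format(object$pindex, digits = 3))) +
    ggplot2::ylim(0, 1)
}
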