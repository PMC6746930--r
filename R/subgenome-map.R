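#' Partition collinear blocks into subgenome tracks
#'
#' Greedily tiles the collinear blocks found between a polyploidy-affected
#' genome and its outgroup reference into `S` tracks along each reference
#' chromosome, so that each track approximates one subgenome. Blocks are
#' processed in a deterministic order (descending anchor count, ties broken
#' by longer reference interval, query chromosome name, reference start) and
#' placed on the lowest-index track where fewer than `overlap_frac` of the
#' block's anchor positions are already occupied; anchors falling on
#' already-occupied ranks are trimmed from the newcomer. Blocks that fit no
#' track are discarded with a warning.
#'
#' The tiler is deterministic (stable sorts, no randomness) but does not
#' link track indices across reference chromosomes, and cannot join blocks
#' of one subgenome across tracks when their reference intervals are
#' disjoint; published per-track anchor files can bypass it via
#' [as_subgenome_assignment()].
#'
#' @param anchors A `collinear_tbl` from [read_collinearity()].
#' @param ref Reference genome `gene_tbl`.
#' @param S Number of subgenomes (>= 2).
#' @param overlap_frac Tolerated fraction of a block's anchors overlapping
#'   already-placed ranks (default 0.10).
#' @return A tibble of class `subgenome_assignment` with one row per
#'   (reference gene, track): columns `ref_chrom`, `ref_rank`, `ref_gene`,
#'   `track`, `qry_gene` (`NA` = lost), `block_id`; attribute `S`.
#' @export
partition_subgenomes <- function(anchors, ref, S = 2, overlap_frac = 0.10) {
  if (S < 2) abort("S must be >= 2")
  blocks <- summarize_blocks(anchors) |>
    mutate(ref_span = .data$ref_hi - .data$ref_lo) |>
    arrange(dplyr::desc(.data$n_anchors), dplyr::desc(.data$ref_span),
            .data$qry_chrom, .data$ref_lo)
  anchor_split <- split(as_tibble(anchors), anchors$block_id)
  ref_df <- as_tibble(ref)
  chrom_sizes <- ref_df |>
    group_by(ref_chrom = .data$chrom) |>
    summarise(n = max(.data$rank) + 1L, .groups = "drop")
  covered <- unique(blocks$ref_chrom)
  missing_chroms <- setdiff(chrom_sizes$ref_chrom, covered)
  if (length(missing_chroms) > 0) {
    warn(paste0("no collinear blocks on reference chromosome(s): ",
                paste(missing_chroms, collapse = ", "), "; omitted"))
  }
  occupied <- list() # [[chrom]][[track]] logical over ranks
  placed <- vector("list", nrow(blocks))
  n_discarded <- 0L
  for (b in seq_len(nrow(blocks))) {
    cc <- blocks$ref_chrom[b]
    n <- chrom_sizes$n[match(cc, chrom_sizes$ref_chrom)]
    if (is.null(occupied[[cc]])) {
      occupied[[cc]] <- lapply(seq_len(S), function(i) logical(n))
    }
    a <- anchor_split[[blocks$block_id[b]]]
    a <- a[a$ref_chrom == cc, ]
    pos <- a$ref_rank + 1L
    placed_track <- NA_integer_
    for (t in seq_len(S)) {
      ov <- sum(occupied[[cc]][[t]][pos]) / length(pos)
      if (ov < overlap_frac) { placed_track <- t; break }
    }
    if (is.na(placed_track)) {
      n_discarded <- n_discarded + 1L
      next
    }
    # residual anchors on already-occupied ranks are trimmed from the
    # newcomer; the block then occupies its whole rank interval, so later
    # blocks see interval coverage, not just anchor positions
    free <- !occupied[[cc]][[placed_track]][pos]
    span <- (blocks$ref_lo[b] + 1L):blocks$ref_hi[b]
    occupied[[cc]][[placed_track]][span] <- TRUE
    placed[[b]] <- a[free, ] |> mutate(track = placed_track)
  }
  if (n_discarded > 0) {
    warn(paste0(n_discarded, " unplaceable block(s) discarded"))
  }
  placed <- list_rbind(placed[!vapply(placed, is.null, TRUE)])
  if (is.null(placed) || nrow(placed) == 0) {
    abort("no block could be placed on any track")
  }
  empty_tracks <- setdiff(seq_len(S), unique(placed$track))
  if (length(empty_tracks) > 0) {
    warn(paste0("track(s) with no placed block: ",
                paste(empty_tracks, collapse = ", ")))
  }
  grid <- ref_df |>
    filter(.data$chrom %in% unique(placed$ref_chrom)) |>
    select(ref_chrom = "chrom", ref_rank = "rank", ref_gene = "gene_id") |>
    tidyr::expand_grid(track = seq_len(S))
  out <- grid |>
    left_join(
      placed |> select("ref_chrom", "ref_rank", "track",
                       "qry_gene", "block_id"),
      by = c("ref_chrom", "ref_rank", "track")
    ) |>
    arrange(.data$ref_chrom, .data$ref_rank, .data$track)
  new_subgenome_assignment(out, S)
}

new_subgenome_assignment <- function(df, S) {
  df <- as_tibble(df)
  attr(df, "S") <- S
  class(df) <- c("subgenome_assignment", class(df))
  df
}

#' Build a subgenome assignment from per-track anchors
#'
#' Bypasses the greedy tiler when subgenome membership is already known
#' (published assignments, simulation truth): takes anchors that already
#' carry a `track` column and expands them over the full reference gene grid.
#'
#' @param anchors Data frame with columns `ref_chrom`, `ref_rank`,
#'   `qry_gene`, `track` (and optionally `block_id`).
#' @param ref Reference genome `gene_tbl`.
#' @param S Number of subgenomes; defaults to the number of distinct tracks.
#' @return A `subgenome_assignment` tibble.
#' @export
as_subgenome_assignment <- function(anchors, ref, S = NULL) {
  anchors <- as_tibble(anchors)
  S <- S %||% n_distinct(anchors$track)
  if (S < 2) abort("S must be >= 2")
  if (!("block_id" %in% names(anchors))) anchors$block_id <- NA_character_
  dup <- anchors |>
    count(.data$ref_chrom, .data$ref_rank, .data$track) |>
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort("more than one retained gene for a (reference rank, track) pair")
  }
  grid <- as_tibble(ref) |>
    filter(.data$chrom %in% unique(anchors$ref_chrom)) |>
    select(ref_chrom = "chrom", ref_rank = "rank", ref_gene = "gene_id") |>
    tidyr::expand_grid(track = seq_len(S))
  out <- grid |>
    left_join(anchors |> select("ref_chrom", "ref_rank", "track",
                                "qry_gene", "block_id"),
              by = c("ref_chrom", "ref_rank", "track")) |>
    arrange(.data$ref_chrom, .data$ref_rank, .data$track)
  new_subgenome_assignment(out, S)
}

#' Order subgenome tracks by dominance
#'
#' Ranks tracks by total retained gene count, most-retained (dominant)
#' first. Chromosomes with higher gene loss belong to the sensitive
#' subgenome, the others to the dominant one; exact ties keep the input
#' track order, making the arbitrary assignment deterministic.
#'
#' @param assignment A `subgenome_assignment`.
#' @return The assignment with a `dominance` attribute: a tibble with
#'   columns `track`, `retained`, `dominance_rank` (1 = dominant), also
#'   retrievable with [dominance_order()].
#' @export
label_dominance <- function(assignment) {
  counts <- as_tibble(assignment) |>
    group_by(.data$track) |>
    summarise(retained = sum(!is.na(.data$qry_gene)), .groups = "drop") |>
    arrange(.data$track)
  ord <- order(-counts$retained, counts$track)
  counts$dominance_rank <- match(seq_len(nrow(counts)), ord)
  attr(assignment, "dominance") <- counts
  assignment
}

#' @rdname label_dominance
#' @export
dominance_order <- function(assignment) {
  dom <- attr(assignment, "dominance")
  if (is.null(dom)) dom <- attr(label_dominance(assignment), "dominance")
  dom$track[order(dom$dominance_rank)]
}

#' @export
print.subgenome_assignment <- function(x, ...) {
  S <- attr(x, "S")
  retained <- sum(!is.na(x$qry_gene))
  cat("<subgenome assignment>", S, "track(s),",
      n_distinct(x$ref_chrom), "reference chromosome(s),",
      retained, "retained gene placements\n")
  NextMethod()
}

#' Write a subgenome assignment track table
#'
#' @param assignment A `subgenome_assignment`.
#' @param path Output path.
#' @return `path`, invisibly. Lost positions are written as `LOST`.
#' @export
write_tracks <- function(assignment, path) {
  df <- as_tibble(assignment) |>
    mutate(qry_gene = ifelse(is.na(.data$qry_gene), "LOST",
                             .data$qry_gene)) |>
    select("ref_chrom", "ref_rank", "ref_gene", "track", "qry_gene")
  readr::write_tsv(df, path, col_names = TRUE)
  invisible(path)
}
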