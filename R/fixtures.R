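#' Generate a synthetic polyploid test bundle
#'
#' Builds a complete, self-contained test genome: an intact ancestor used as
#' the outgroup reference, `S` fractionated subgenome copies, and every
#' on-disk file the pipeline consumes — reference gene table (BED and GFF3),
#' query gene table (TSV), anchor files (plain TSV and MCScanX-style
#' collinearity) and a truth table recording each gene's subgenome of origin
#' and the planted retention targets.
#'
#' Scenarios:
#' \describe{
#'   \item{`balanced`}{S = 2 copies fractionated to the same target
#'     (default 0.6/0.6): the autopolyploid-like null.}
#'   \item{`biased`}{S = 2 copies with distinct targets (default
#'     0.75/0.40): allopolyploid-like biased fractionation.}
#'   \item{`two_round`}{4 tracks from two nested duplications: an older
#'     biased round (two lineages fractionated to distinct targets) followed
#'     by a younger balanced round within each lineage; pairing
#'     `(1,2) | (3,4)`.}
#'   \item{`decaploid_grouped`}{5 tracks with a planted 2+3 group structure:
#'     a group-level biased round then balanced per-track loss.}
#' }
#'
#' Each subgenome copy is emitted as one query chromosome per reference
#' chromosome. With `shatter = TRUE` the single collinear block per
#' (reference chromosome, copy) is split into 3 segments with breakpoints
#' staggered across copies, so segments of different copies chain-overlap —
#' the hard path for the greedy tiler.
#'
#' @param dir Output directory (created if needed).
#' @param scenario One of `"balanced"`, `"biased"`, `"two_round"`,
#'   `"decaploid_grouped"`.
#' @param n_chromosomes,genes_per_chromosome Ancestor geometry.
#' @param S Number of subgenome copies; defaults to the scenario's natural
#'   value (2, 2, 4, 5).
#' @param retention Per-copy retention targets; scenario defaults apply
#'   when `NULL`. Must have length `S`.
#' @param run_length_p Geometric run-length parameter of the deletions.
#' @param shatter Split each copy's block into staggered segments.
#' @param seed RNG seed; the bundle is fully reproducible from it.
#' @return Invisibly, a list of class `fixture_truth`: `files` (named paths),
#'   `truth` (per-gene tibble: `ref_chrom`, `ref_rank`, `ref_gene`,
#'   `subgenome`, `qry_gene` or `NA`), `retention` (planted targets),
#'   `realized_retention`, `scenario`, `pairing`/`groups` where applicable,
#'   and `seed`.
#' @export
make_polyploid_fixture <- function(dir,
                                   scenario = c("balanced", "biased",
                                                "two_round",
                                                "decaploid_grouped"),
                                   n_chromosomes = 10,
                                   genes_per_chromosome = 2000,
                                   S = NULL, retention = NULL,
                                   run_length_p = 0.5,
                                   shatter = FALSE, seed = 1) {
  scenario <- match.arg(scenario)
  defaults <- switch(scenario,
    balanced = list(S = 2L, retention = c(0.6, 0.6)),
    biased = list(S = 2L, retention = c(0.75, 0.40)),
    two_round = list(S = 4L, retention = NULL),
    decaploid_grouped = list(S = 5L, retention = NULL)
  )
  S <- S %||% defaults$S
  retention <- retention %||% defaults$retention
  if (!is.null(retention) && length(retention) != S) {
    abort("retention must have one value per subgenome copy")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  n <- genes_per_chromosome
  pairing <- NULL
  groups <- NULL
  # per chromosome: n x S retention masks
  masks <- vector("list", n_chromosomes)
  for (ci in seq_len(n_chromosomes)) {
    m <- NULL
    if (scenario %in% c("balanced", "biased")) {
      m <- do.call(cbind, lapply(seq_len(S), function(k) {
        as.vector(simulate_losses(n, retention[k], run_length_p))
      }))
    } else if (scenario == "two_round") {
      pairing <- list(c(1L, 2L), c(3L, 4L))
      lineage_r <- c(0.85, 0.55)
      track_r <- 0.75
      lin_mask <- lapply(1:2, function(l) {
        as.vector(simulate_losses(n, lineage_r[l], run_length_p))
      })
      m <- do.call(cbind, lapply(1:4, function(k) {
        lin <- if (k <= 2) 1L else 2L
        lin_mask[[lin]] &
          as.vector(simulate_losses(n, track_r, run_length_p))
      }))
      retention <- rep(lineage_r, each = 2) * track_r
    } else if (scenario == "decaploid_grouped") {
      groups <- list(c(1L, 2L), c(3L, 4L, 5L))
      group_r <- c(0.85, 0.55)
      track_r <- 0.75
      grp_mask <- lapply(1:2, function(g) {
        as.vector(simulate_losses(n, group_r[g], run_length_p))
      })
      m <- do.call(cbind, lapply(1:5, function(k) {
        g <- if (k <= 2) 1L else 2L
        grp_mask[[g]] &
          as.vector(simulate_losses(n, track_r, run_length_p))
      }))
      retention <- rep(group_r, c(2, 3)) * track_r
    }
    masks[[ci]] <- m
  }
  names(masks) <- paste0("rc", seq_len(n_chromosomes))

  # reference gene table (BED is 0-based half-open)
  ref_genes <- list_rbind(imap(masks, function(m, cc) {
    r <- seq_len(nrow(m)) - 1L
    tibble(gene_id = paste0("anc", sub("^rc", "", cc), "g", r),
           chrom = cc, start = r * 1000L + 1L, end = r * 1000L + 500L,
           strand = "+", rank = r)
  }))
  bed_path <- file.path(dir, "reference.bed")
  writeLines(paste(ref_genes$chrom, ref_genes$start - 1L, ref_genes$end,
                   ref_genes$gene_id, 0L, ref_genes$strand, sep = "\t"),
             bed_path)
  gff_path <- file.path(dir, "reference.gff3")
  writeLines(c("##gff-version 3",
               paste(ref_genes$chrom, "pindexr", "gene", ref_genes$start,
                     ref_genes$end, ".", ref_genes$strand, ".",
                     paste0("ID=", ref_genes$gene_id), sep = "\t")),
             gff_path)

  # query genes: one chromosome per (ref chromosome, copy); retained only
  truth <- list_rbind(imap(masks, function(m, cc) {
    cnum <- sub("^rc", "", cc)
    list_rbind(lapply(seq_len(S), function(k) {
      r <- seq_len(nrow(m)) - 1L
      tibble(
        ref_chrom = cc, ref_rank = r,
        ref_gene = paste0("anc", cnum, "g", r),
        subgenome = k,
        qry_chrom = paste0("qc", cnum, "s", k),
        qry_gene = ifelse(m[, k], paste0("anc", cnum, "g", r, "_s", k),
                          NA_character_)
      )
    }))
  }))
  qry_genes <- truth |>
    filter(!is.na(.data$qry_gene)) |>
    group_by(.data$qry_chrom) |>
    mutate(qrank = row_number() - 1L) |>
    ungroup()
  qry_path <- file.path(dir, "query_genes.tsv")
  writeLines(c("gene_id\tchrom\tstart\tend\tstrand",
               paste(qry_genes$qry_gene, qry_genes$qry_chrom,
                     qry_genes$qrank * 1000L + 1L,
                     qry_genes$qrank * 1000L + 500L, "+", sep = "\t")),
             qry_path)

  # anchors; block structure per (ref chromosome, copy), optionally
  # shattered into 3 staggered segments
  anchors <- qry_genes |>
    mutate(block_id = block_ids_for(.data$ref_chrom, .data$ref_rank,
                                    .data$subgenome, n, shatter))
  anchor_path <- file.path(dir, "anchors.tsv")
  writeLines(c("ref_gene\tqry_gene\tblock_id",
               paste(anchors$ref_gene, anchors$qry_gene,
                     anchors$block_id, sep = "\t")),
             anchor_path)
  mcs_path <- file.path(dir, "anchors.collinearity")
  write_mcscanx(anchors, mcs_path)

  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(truth, truth_path, col_names = TRUE)

  realized <- truth |>
    group_by(.data$subgenome) |>
    summarise(retention = mean(!is.na(.data$qry_gene)), .groups = "drop")

  invisible(structure(
    list(
      files = c(reference_bed = bed_path, reference_gff3 = gff_path,
                query_genes = qry_path, anchors_tsv = anchor_path,
                collinearity = mcs_path, truth = truth_path),
      truth = truth,
      retention = retention,
      realized_retention = realized,
      scenario = scenario, S = S,
      pairing = pairing, groups = groups,
      run_length_p = run_length_p, seed = seed
    ),
    class = "fixture_truth"
  ))
}

# staggered segment breakpoints: copy k's segment boundaries are shifted so
# its segments always chain-overlap the other copies' segments
block_ids_for <- function(ref_chrom, ref_rank, subgenome, n, shatter) {
  if (!shatter) {
    return(paste0(ref_chrom, "_s", subgenome))
  }
  b1 <- pmax(1, round(n * (0.50 - 0.05 * (subgenome - 1))))
  b2 <- pmin(n - 1, round(n * (0.80 - 0.05 * (subgenome - 1))))
  seg <- 1L + (ref_rank >= b1) + (ref_rank >= b2)
  paste0(ref_chrom, "_s", subgenome, "_seg", seg)
}

write_mcscanx <- function(anchors, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("############### Parameters ###############",
               "# MATCH_SIZE: 5", "# E_VALUE: 1e-05",
               "###########################################"), con)
  blocks <- split(anchors, anchors$block_id)
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    writeLines(sprintf("## Alignment %s: score=%.1f e_value=0 N=%d %s&%s plus",
                       names(blocks)[bi], nrow(b) * 50, nrow(b),
                       b$ref_chrom[1], b$qry_chrom[1]), con)
    writeLines(sprintf("%3d-%3d:\t%s\t%s\t0", bi - 1,
                       seq_len(nrow(b)) - 1, b$ref_gene, b$qry_gene), con)
  }
  invisible(path)
}

#' Evaluate subgenome recovery against fixture truth
#'
#' Compares a `subgenome_assignment` with the truth table of
#' [make_polyploid_fixture()]. Because the greedy tiler does not link track
#' indices across reference chromosomes, tracks are matched to planted
#' subgenomes per chromosome by the best label permutation, and accuracy is
#' the fraction of retained gene placements assigned to their matched
#' subgenome.
#'
#' @param assignment A `subgenome_assignment`.
#' @param truth The `truth` tibble of a fixture bundle.
#' @return Anchor-weighted accuracy in \[0, 1\].
#' @export
subgenome_recovery <- function(assignment, truth) {
  placed <- as_tibble(assignment) |>
    filter(!is.na(.data$qry_gene)) |>
    left_join(truth |>
                filter(!is.na(.data$qry_gene)) |>
                select("qry_gene", "subgenome"),
              by = "qry_gene")
  per_chrom <- split(placed, placed$ref_chrom)
  hits <- 0L
  total <- 0L
  for (ch in per_chrom) {
    tab <- table(ch$track, ch$subgenome)
    perms <- all_permutations(ncol(tab))
    best <- 0L
    for (p in perms) {
      s <- sum(vapply(seq_len(min(nrow(tab), length(p))), function(i) {
        if (p[i] <= ncol(tab) && i <= nrow(tab)) tab[i, p[i]] else 0L
      }, 0L))
      best <- max(best, s)
    }
    hits <- hits + best
    total <- total + sum(tab)
  }
  hits / total
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in all_permutations(k - 1L)) {
      tail <- seq_len(k)[-i][rest]
      out[[length(out) + 1L]] <- c(i, tail)
    }
  }
  out
}
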