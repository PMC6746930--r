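#' Read collinear anchor pairs
#'
#' Reads the output of a synteny/collinearity caller into a table of anchor
#' gene pairs, resolving every gene id against the reference and query gene
#' tables and attaching chromosome and rank coordinates. The collinearity
#' computation itself (BLAST homolog search, block chaining) is out of scope:
#' its output files are consumed here.
#'
#' Dialects:
#' \describe{
#'   \item{`mcscanx`}{MCScanX-style ".collinearity": block headers of the
#'     form `## Alignment 0: ...` (a colon after "Alignment" is also
#'     accepted), anchor lines of whitespace-separated fields with the two
#'     gene ids in the first two non-index fields; a trailing e-value column
#'     is optional; `#`-prefixed lines other than block headers are ignored.}
#'   \item{`tsv`}{three columns `ref_gene`, `qry_gene`, `block_id`, with or
#'     without a header.}
#' }
#'
#' Anchors whose first gene resolves in the query table and second in the
#' reference table are silently swapped, so either column order works.
#'
#' @param path Path to the collinearity file.
#' @param dialect `"mcscanx"` or `"tsv"`.
#' @param ref Reference genome `gene_tbl` (see [read_gene_positions()]).
#' @param qry Query (polyploidy-affected) genome `gene_tbl`.
#' @return A tibble of class `collinear_tbl` with one row per anchor:
#'   `block_id`, `ref_gene`, `ref_chrom`, `ref_rank`, `qry_gene`,
#'   `qry_chrom`, `qry_rank`. Blocks with fewer than 2 anchors trigger a
#'   warning but are kept.
#' @seealso [summarize_blocks()] for per-block intervals and orientation.
#' @export
read_collinearity <- function(path, dialect = c("mcscanx", "tsv"), ref, qry) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("collinearity file not found: ", path))
  }
  pairs <- switch(dialect,
    mcscanx = parse_collinearity_mcscanx(path),
    tsv = parse_collinearity_tsv(path)
  )
  if (nrow(pairs) == 0) abort(paste0("no anchors parsed from ", path))
  resolve_anchors(pairs, ref, qry)
}

parse_collinearity_tsv <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) > 0 && grepl("^ref_gene\t", lines[1])) lines <- lines[-1]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    abort(paste0("unparseable anchor TSV line ",
                 which(lengths(fields) < 3)[1],
                 ": expected ref_gene, qry_gene, block_id"))
  }
  tibble(
    ref_gene = vapply(fields, `[`, "", 1L),
    qry_gene = vapply(fields, `[`, "", 2L),
    block_id = vapply(fields, `[`, "", 3L)
  )
}

parse_collinearity_mcscanx <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- grepl("^##\\s*Alignment", lines)
  block <- rep(NA_character_, length(lines))
  ids <- stringr::str_match(lines[hdr], "Alignment:?\\s+(\\S+?):?\\s")[, 2]
  # headers like "## Alignment 0: score=..." or "## Alignment: 0 ..."
  ids[is.na(ids)] <-
    stringr::str_match(lines[hdr][is.na(ids)], "Alignment:?\\s+(\\S+)")[, 2]
  block[hdr] <- sub(":$", "", ids)
  block <- cumfill(block)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(tibble(ref_gene = character(),
                                qry_gene = character(),
                                block_id = character()))
  if (anyNA(block[keep])) {
    abort(paste0("anchor line ", which(keep & is.na(block))[1],
                 " before any '## Alignment' header"))
  }
  anchor <- lines[keep]
  # strip MCScanX anchor index prefix "  0-  0:"
  anchor <- sub("^\\s*\\d+[-\\s]\\s*\\d+:\\s*", "", anchor)
  fields <- strsplit(trimws(anchor), "\\s+")
  short <- lengths(fields) < 2
  if (any(short)) {
    abort(paste0("unparseable collinearity line ",
                 which(keep)[short][1], ": fewer than 2 gene fields"))
  }
  tibble(
    ref_gene = vapply(fields, `[`, "", 1L),
    qry_gene = vapply(fields, `[`, "", 2L),
    block_id = block[keep]
  )
}

cumfill <- function(x) {
  # carry last non-NA value forward
  i <- seq_along(x)
  has <- !is.na(x)
  if (!any(has)) return(x)
  idx <- cummax(ifelse(has, i, 0L))
  out <- rep(NA_character_, length(x))
  out[idx > 0L] <- x[idx[idx > 0L]]
  out
}

resolve_anchors <- function(pairs, ref, qry) {
  ref_ids <- setNames(seq_len(nrow(ref)), ref$gene_id)
  qry_ids <- setNames(seq_len(nrow(qry)), qry$gene_id)
  a_in_ref <- pairs$ref_gene %in% ref$gene_id
  b_in_qry <- pairs$qry_gene %in% qry$gene_id
  swap <- !a_in_ref & (pairs$ref_gene %in% qry$gene_id) &
    (pairs$qry_gene %in% ref$gene_id)
  if (any(swap)) {
    tmp <- pairs$ref_gene[swap]
    pairs$ref_gene[swap] <- pairs$qry_gene[swap]
    pairs$qry_gene[swap] <- tmp
  }
  unresolved <- unique(c(
    pairs$ref_gene[!(pairs$ref_gene %in% ref$gene_id)],
    pairs$qry_gene[!(pairs$qry_gene %in% qry$gene_id)]
  ))
  if (length(unresolved) > 0) {
    abort(paste0(
      length(unresolved), " gene id(s) not resolvable; first offenders: ",
      paste(head(unresolved, 10), collapse = ", ")
    ))
  }
  ri <- ref_ids[pairs$ref_gene]
  qi <- qry_ids[pairs$qry_gene]
  out <- tibble(
    block_id = pairs$block_id,
    ref_gene = pairs$ref_gene,
    ref_chrom = ref$chrom[ri],
    ref_rank = ref$rank[ri],
    qry_gene = pairs$qry_gene,
    qry_chrom = qry$chrom[qi],
    qry_rank = qry$rank[qi]
  )
  small <- out |> count(.data$block_id) |> filter(n < 2)
  if (nrow(small) > 0) {
    warn(paste0(nrow(small), " block(s) with < 2 anchors kept: ",
                paste(head(small$block_id, 10), collapse = ", ")))
  }
  class(out) <- c("collinear_tbl", class(out))
  out
}

#' Summarize collinear blocks
#'
#' Collapses an anchor table into one row per block, with half-open 0-based
#' rank intervals computed from member anchors and orientation inferred from
#' the direction of query ranks along the reference (single-anchor blocks get
#' orientation `"+"` by convention).
#'
#' @param anchors A `collinear_tbl` from [read_collinearity()].
#' @return A tibble with columns `block_id`, `ref_chrom`, `ref_lo`,
#'   `ref_hi`, `qry_chrom`, `qry_lo`, `qry_hi`, `orientation`, `n_anchors`.
#' @export
summarize_blocks <- function(anchors) {
  anchors |>
    group_by(.data$block_id) |>
    summarise(
      ref_chrom = first(.data$ref_chrom),
      ref_lo = min(.data$ref_rank),
      ref_hi = max(.data$ref_rank) + 1L,
      qry_chrom = first(.data$qry_chrom),
      qry_lo = min(.data$qry_rank),
      qry_hi = max(.data$qry_rank) + 1L,
      orientation = block_orientation(.data$ref_rank, .data$qry_rank),
      n_anchors = n(),
      .groups = "drop"
    )
}

block_orientation <- function(ref_rank, qry_rank) {
  if (length(ref_rank) < 2) return("+")
  o <- order(ref_rank)
  d <- diff(qry_rank[o])
  if (sum(d < 0) > sum(d > 0)) "-" else "+"
}

#' Write anchors as a plain TSV
#'
#' @param anchors A `collinear_tbl` or data frame with `ref_gene`,
#'   `qry_gene`, `block_id` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anchor_tsv <- function(anchors, path) {
  readr::write_tsv(
    as_tibble(anchors)[, c("ref_gene", "qry_gene", "block_id")],
    path, col_names = TRUE
  )
  invisible(path)
}
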