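#' Read a gene position table
#'
#' Reads gene loci from a GFF3, BED6 or plain TSV file and returns an ordered
#' gene table with a 0-based rank per chromosome. Rank order follows start
#' coordinate, with ties broken by end coordinate and then gene id, so that a
#' given input always yields the same ordering. Gene rank, not base-pair
#' position, is the coordinate used by every downstream computation: windows
#' are gene-count windows, which removes assembly-scale effects.
#'
#' Dialects:
#' \describe{
#'   \item{`gff3`}{standard GFF3; only features of type `gene` are used
#'     (all features are used when no `gene` rows are present). The gene id is
#'     taken from the `ID` attribute, falling back to `Name`.}
#'   \item{`bed`}{BED with at least 4 columns (chrom, start, end, name);
#'     column 6 is used as strand when present. BED starts are 0-based and are
#'     converted to 1-based.}
#'   \item{`tsv`}{five columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'     with or without a header line.}
#' }
#'
#' @param path Path to the input file.
#' @param dialect One of `"gff3"`, `"bed"`, `"tsv"`.
#' @param genome_label Label stored on the returned table; defaults to the
#'   file name without extension.
#' @return A tibble of class `gene_tbl` with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `rank`. Ranks are consecutive `0..n-1` within
#'   each chromosome.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("g2\tchr1\t50\t60\t+", "g1\tchr1\t100\t120\t-"), tf)
#' read_gene_positions(tf, "tsv")
#' @export
read_gene_positions <- function(path, dialect = c("gff3", "bed", "tsv"),
                                genome_label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("gene position file not found: ", path))
  }
  genome_label <- genome_label %||%
    sub("\\.[^.]*$", "", basename(path))
  raw <- switch(dialect,
    gff3 = parse_genes_gff3(path),
    bed  = parse_genes_bed(path),
    tsv  = parse_genes_tsv(path)
  )
  if (nrow(raw) == 0) {
    abort(paste0("no gene records parsed from ", path))
  }
  dup <- raw$gene_id[duplicated(raw$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene id(s): ",
                 paste(unique(head(dup, 10)), collapse = ", ")))
  }
  bad <- which(raw$start > raw$end)
  if (length(bad) > 0) {
    abort(paste0("start > end for gene ", raw$gene_id[bad[1]]))
  }
  out <- raw |>
    arrange(.data$chrom, .data$start, .data$end, .data$gene_id) |>
    group_by(.data$chrom) |>
    mutate(rank = row_number() - 1L) |>
    ungroup()
  new_gene_tbl(out, genome_label)
}

new_gene_tbl <- function(x, genome_label) {
  x <- as_tibble(x)[, c("gene_id", "chrom", "start", "end", "strand", "rank")]
  attr(x, "genome_label") <- genome_label
  class(x) <- c("gene_tbl", class(x))
  x
}

#' @export
print.gene_tbl <- function(x, ...) {
  cat("<gene position table> genome:", attr(x, "genome_label") %||% "?",
      "|", nrow(x), "genes on", n_distinct(x$chrom), "chromosome(s)\n")
  NextMethod()
}

parse_genes_gff3 <- function(path) {
  g <- ape::read.gff(path, GFF3 = TRUE)
  if (nrow(g) == 0) abort(paste0("empty GFF3 file: ", path))
  if (any(g$type == "gene")) g <- g[g$type == "gene", , drop = FALSE]
  att <- as.character(g$attributes)
  id <- stringr::str_match(att, "(?:^|;)\\s*ID=([^;]+)")[, 2]
  nm <- stringr::str_match(att, "(?:^|;)\\s*Name=([^;]+)")[, 2]
  id <- ifelse(is.na(id), nm, id)
  if (anyNA(id)) {
    abort("GFF3 gene feature without ID or Name attribute")
  }
  tibble(
    gene_id = id,
    chrom = as.character(g$seqid),
    start = as.integer(g$start),
    end = as.integer(g$end),
    strand = clean_strand(as.character(g$strand))
  )
}

parse_genes_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(paste0("empty BED file: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4)) {
    abort(paste0("unparseable BED line ", which(nf < 4)[1],
                 ": fewer than 4 columns"))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    abort(paste0("unparseable BED line ",
                 which(is.na(start) | is.na(end))[1],
                 ": non-numeric coordinates"))
  }
  strand <- vapply(seq_along(fields), function(i) {
    if (nf[i] >= 6) fields[[i]][6] else "."
  }, "")
  tibble(
    gene_id = vapply(fields, `[`, "", 4L),
    chrom = vapply(fields, `[`, "", 1L),
    start = start + 1L,
    end = end,
    strand = clean_strand(strand)
  )
}

parse_genes_tsv <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) abort(paste0("empty gene TSV file: ", path))
  if (grepl("^gene_id\t", lines[1])) lines <- lines[-1]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4)) {
    abort(paste0("unparseable gene TSV line ", which(nf < 4)[1],
                 ": expected gene_id, chrom, start, end[, strand]"))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4L)))
  if (anyNA(start) || anyNA(end)) {
    abort(paste0("unparseable gene TSV line ",
                 which(is.na(start) | is.na(end))[1],
                 ": non-numeric coordinates"))
  }
  strand <- vapply(seq_along(fields), function(i) {
    if (nf[i] >= 5) fields[[i]][5] else "."
  }, "")
  tibble(
    gene_id = vapply(fields, `[`, "", 1L),
    chrom = vapply(fields, `[`, "", 2L),
    start = start,
    end = end,
    strand = clean_strand(strand)
  )
}

clean_strand <- function(x) {
  x[is.na(x) | !(x %in% c("+", "-"))] <- "."
  x
}

#' Write a gene position table as TSV
#'
#' @param genes A `gene_tbl` (or data frame with the same columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_positions <- function(genes, path) {
  readr::write_tsv(
    as_tibble(genes)[, c("gene_id", "chrom", "start", "end", "strand")],
    path, col_names = TRUE
  )
  invisible(path)
}
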