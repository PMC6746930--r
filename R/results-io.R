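#' Write a P-index result to a structured text report
#'
#' The report is a key/value header (statistic, status, mode, parameters)
#' followed by a per-chromosome table (window counts, informative counts,
#' term, weight). Numbers are written with enough precision for a lossless
#' round trip through [read_pindex_result()].
#'
#' @param result A `pindex_result` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pindex_result <- function(result, path) {
  stopifnot(inherits(result, "pindex_result"))
  num <- function(x) sprintf("%.17g", x)
  params <- result$params
  hdr <- c(
    "# pindexr result",
    paste0("pindex\t", num(result$pindex)),
    paste0("status\t", result$status),
    paste0("mode\t", result$mode),
    vapply(names(params), function(k) {
      v <- params[[k]]
      paste0("param.", k, "\t",
             if (is.numeric(v)) paste(num(v), collapse = ",")
             else paste(as.character(v), collapse = ","))
    }, "")
  )
  ch <- result$chromosomes
  body <- c(
    "[chromosomes]",
    paste("chrom", "n_windows", "n_informative", "term", "weight",
          sep = "\t"),
    if (nrow(ch) > 0) {
      paste(ch$chrom, ch$n_windows, ch$n_informative,
            num(ch$term), num(ch$weight), sep = "\t")
    }
  )
  tryCatch(
    writeLines(c(hdr, "", body), path),
    error = function(e) abort(paste0("cannot write result to ", path))
  )
  invisible(path)
}

#' Read a P-index result report
#'
#' Parses a file written by [write_pindex_result()] back into a
#' `pindex_result` object.
#'
#' @param path Path to the report file.
#' @return A `pindex_result` object.
#' @export
read_pindex_result <- function(path) {
  lines <- readr::read_lines(path)
  sec <- which(lines == "[chromosomes]")
  if (length(sec) != 1) abort(paste0("malformed result file: ", path))
  hdr <- lines[seq_len(sec - 1)]
  hdr <- hdr[!grepl("^#", hdr) & nzchar(hdr)]
  kv <- strsplit(hdr, "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  get <- function(k) vals[match(k, keys)]
  params <- list()
  for (i in which(startsWith(keys, "param."))) {
    k <- sub("^param\\.", "", keys[i])
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    vn <- suppressWarnings(as.numeric(v))
    params[[k]] <- if (anyNA(vn)) v else vn
  }
  body <- lines[(sec + 2):length(lines)]
  body <- body[nzchar(body)]
  ch <- if (length(body) > 0) {
    f <- strsplit(body, "\t", fixed = TRUE)
    tibble(
      chrom = vapply(f, `[`, "", 1L),
      n_windows = as.integer(vapply(f, `[`, "", 2L)),
      n_informative = as.integer(vapply(f, `[`, "", 3L)),
      term = as.numeric(vapply(f, `[`, "", 4L)),
      weight = as.numeric(vapply(f, `[`, "", 5L))
    )
  } else {
    tibble(chrom = character(), n_windows = integer(),
           n_informative = integer(), term = numeric(), weight = numeric())
  }
  new_pindex_result(
    pindex = as.numeric(get("pindex")),
    status = get("status"),
    mode = get("mode"),
    chromosomes = ch,
    params = params
  )
}
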