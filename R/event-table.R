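#' Catalog of published angiosperm polyploidy events
#'
#' Returns the packaged catalog of 24 numbered paleopolyploidy events, each
#' with one or more (checked genome, reference genome, P-index) rows as
#' printed in the source compilation, and the printed polyploidy nature where
#' one was given (events 3 and 4 were left unlabeled). P-index values are
#' kept exactly as printed, to two decimals.
#'
#' @return A tibble of class `event_tbl` with columns `event` (1..24),
#'   `event_name`, `checked_genome`, `reference_genome`, `pindex`,
#'   `printed_nature` (`"Allo"`, `"Auto"` or `NA`).
#' @seealso [read_event_table()], [classify_event_table()]
#' @export
polyploidy_events <- function() {
  rows <- list(
    list(1L, "Brassica-common hexaploidy", "Allo", list(
      c("B. oleracea", "A. thaliana", "0.85"),
      c("B. rapa", "A. thaliana", "0.82"))),
    list(2L, "B. napus-specific tetraploidy", "Allo", list(
      c("B. napus", "B. rapa", "0.78"),
      c("B. napus", "B. oleracea", "0.76"))),
    list(3L, "Arabidopsis tetraploidy 1", NA_character_, list(
      c("A. thaliana", "V. vinifera", "0.34"),
      c("A. lyrata", "V. vinifera", "0.36"))),
    list(4L, "Arabidopsis tetraploidy 2", NA_character_, list(
      c("A. thaliana", "V. vinifera", "0.41"),
      c("A. lyrata", "V. vinifera", "0.50"))),
    list(5L, "Solanaceae-common hexaploidy", "Allo", list(
      c("S. lycopersicum", "C. canephora", "0.53"),
      c("S. tuberosum", "C. canephora", "0.56"),
      c("C. annuum", "C. canephora", "0.50"),
      c("C. annuum", "V. vinifera", "0.48"),
      c("S. melongena", "C. canephora", "0.47"))),
    list(6L, "Gossypium-common decaploidy", "Allo", list(
      c("G. raimondii", "T. cacao", "0.47"),
      c("G. raimondii", "V. vinifera", "0.57"),
      c("G. arboreum", "T. cacao", "0.42"),
      c("G. arboreum", "V. vinifera", "0.51"))),
    list(7L, "Gossypium tetraploidy", "Allo", list(
      c("G. hirsutum", "G. raimondii", "0.70"))),
    list(8L, "Fabaceae-common tetraploidy", "Allo", list(
      c("M. truncatula", "V. vinifera", "0.39"),
      c("V. radiata", "V. vinifera", "0.45"),
      c("V. angularis", "V. vinifera", "0.49"),
      c("C. arietium", "V. vinifera", "0.42"),
      c("P. vulgaris", "V. vinifera", "0.42"),
      c("L. japonicus", "V. vinifera", "0.50"),
      c("C. cajan", "V. vinifera", "0.36"),
      c("A. ipaensis", "V. vinifera", "0.48"),
      c("A. duranensis", "V. vinifera", "0.51"))),
    list(9L, "Soybean-specific tetraploidy", "Auto", list(
      c("G. max", "M. truncatula", "0.17"))),
    list(10L, "Cucurbitaceae-common tetraploidy", "Allo", list(
      c("C. lanatus", "V. vinifera", "0.38"),
      c("C. sativus", "V. vinifera", "0.56"),
      c("C. melo", "V. vinifera", "0.67"))),
    list(11L, "Apple-specific autotetraploidy", "Auto", list(
      c("M. domestica", "P. persica", "0.22"),
      c("M. domestica", "P. mume", "0.22"))),
    list(12L, "Poplar-specific autotetraploidy", "Auto", list(
      c("P. trichocarpa", "P. persica", "0.26"))),
    list(13L, "Major eudicot-common hexaploidy", "Allo", list(
      c("V. vinifera", "V. vinifera", "0.79"))),
    list(14L, "Grass-common tetraploidy", "Allo", list(
      c("O. sativa", "A. comosus", "0.43"),
      c("S. bicolor", "A. comosus", "0.41"),
      c("S. italica", "A. comosus", "0.44"),
      c("B. distachyon", "A. comosus", "0.39"))),
    list(15L, "Zea-specific tetraploidy", "Allo", list(
      c("Z. mays", "O. sativa", "0.84"),
      c("Z. mays", "S. italica", "0.69"),
      c("Z. mays", "S. bicolor", "0.71"))),
    list(16L, "Triticum-specific hexaploidy", "Allo", list(
      c("T. aestivum", "A. tauschii", "0.42"),
      c("T. aestivum", "T. urartu", "0.43"),
      c("T. aestivum-1", "H. vulgare", "0.75"),
      c("T. aestivum-2", "H. vulgare", "0.52"))),
    list(17L, "Ananas tetraploidy", "Allo", list(
      c("A. comosus", "E. guineensis", "0.39"),
      c("A. comosus", "S. polyrhiza", "0.44"),
      c("A. comosus", "V. vinifera", "0.42"))),
    list(18L, "Elaeis-specific tetraploidy", "Allo", list(
      c("E. guineensis", "A. comosus", "0.58"),
      c("E. guineensis", "S. polyrhiza", "0.50"))),
    list(19L, "Commelinids-common tetraploidy", "Allo", list(
      c("E. guineensis", "S. polyrhiza", "0.50"))),
    list(20L, "S. polyrhiza tetraploidy 1", "Allo", list(
      c("S. polyrhiza", "V. vinifera", "0.47"))),
    list(21L, "S. polyrhiza tetraploidy 2", "Allo", list(
      c("S. polyrhiza", "V. vinifera", "0.44"))),
    list(22L, "Musa tetraploidy 1", "Allo", list(
      c("M. acuminata", "E. guineensis", "0.37"))),
    list(23L, "Musa tetraploidy 2", "Allo", list(
      c("M. acuminata", "E. guineensis", "0.35"))),
    list(24L, "Musa tetraploidy 3", "Allo", list(
      c("M. acuminata", "E. guineensis", "0.44")))
  )
  out <- purrr::map(rows, function(ev) {
    vals <- do.call(rbind, ev[[4]])
    tibble(
      event = ev[[1]],
      event_name = ev[[2]],
      checked_genome = vals[, 1],
      reference_genome = vals[, 2],
      pindex = as.numeric(vals[, 3]),
      printed_nature = ev[[3]]
    )
  }) |> list_rbind()
  class(out) <- c("event_tbl", class(out))
  out
}

#' Write the packaged event catalog to a TSV file
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
make_event_table_fixture <- function(path) {
  ev <- polyploidy_events()
  ev$pindex <- sprintf("%.2f", ev$pindex)
  readr::write_tsv(as_tibble(ev), path, col_names = TRUE, na = "")
  invisible(path)
}

#' Read an event table from TSV
#'
#' Reads a table in the format written by [make_event_table_fixture()]:
#' columns `event`, `event_name`, `checked_genome`, `reference_genome`,
#' `pindex`, `printed_nature` (empty for unlabeled events).
#'
#' @param path Path to the TSV file; defaults to the fixture packaged under
#'   `inst/extdata`.
#' @return A tibble of class `event_tbl`.
#' @export
read_event_table <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "polyploidy_events.tsv", package = "pindexr")
  if (!nzchar(path) || !file.exists(path)) {
    abort("event table file not found")
  }
  out <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      event = readr::col_integer(),
      event_name = readr::col_character(),
      checked_genome = readr::col_character(),
      reference_genome = readr::col_character(),
      pindex = readr::col_double(),
      printed_nature = readr::col_character()
    )
  ))
  required <- c("event", "event_name", "checked_genome",
                "reference_genome", "pindex", "printed_nature")
  if (!all(required %in% names(out)) || nrow(out) == 0) {
    abort("malformed event table: expected columns event, event_name, checked_genome, reference_genome, pindex, printed_nature")
  }
  if (anyNA(out$pindex) || any(out$pindex < 0 | out$pindex > 1)) {
    abort("malformed event table: pindex values must lie in [0, 1]")
  }
  class(out) <- c("event_tbl", class(out))
  out
}
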