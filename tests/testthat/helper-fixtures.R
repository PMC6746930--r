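# small on-disk gene tables and anchor files built in code

write_tmp_lines <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

mini_ref <- function() {
  f <- write_tmp_lines(c(
    "g1\tchr1\t100\t150\t+",
    "g2\tchr1\t300\t350\t+",
    "g3\tchr1\t500\t550\t+",
    "g4\tchr1\t700\t750\t+",
    "g5\tchr2\t100\t150\t-",
    "g6\tchr2\t300\t350\t-"
  ))
  read_gene_positions(f, "tsv", genome_label = "ref")
}

mini_qry <- function() {
  f <- write_tmp_lines(c(
    "q1\tqc1\t100\t150\t+",
    "q2\tqc1\t300\t350\t+",
    "q3\tqc1\t500\t550\t+",
    "q4\tqc2\t100\t150\t+",
    "q5\tqc2\t300\t350\t+",
    "q6\tqc2\t500\t550\t+"
  ))
  read_gene_positions(f, "tsv", genome_label = "qry")
}

# shared medium fixture bundles (built once per test run)
fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, ...) {
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- make_polyploid_fixture(
      file.path(tempdir(), paste0("fx_", key)), ...
    )
  }
  fixture_cache[[key]]
}
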