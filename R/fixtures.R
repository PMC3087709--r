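# Packaged transcriptions of the published result tables, used as fixtures
# and worked-example inputs.

fixture_files <- c(
  table1 = "table1_responsive_top20.tsv",
  table2 = "table2_glnr_dependent_top.tsv",
  table3 = "table3_binding_regions.tsv")

#' Load a packaged result-table fixture
#'
#' Three tables transcribed from the published study ship with the package:
#' `table1`, the twenty most strongly induced nitrogen-responsive genes with
#' their fold induction (T30 vs T0) and fold repression (T30 vs T45);
#' `table2`, the strongly induced genes whose response is lost in the glnR
#' mutant; and `table3`, the thirty-six ChIP-chip binding regions with their
#' downstream genes, the mutant-strain transcript fold change, and the
#' annotated consensus sites (several regions carry multiple sites,
#' semicolon-separated; regions without a consensus site carry the literal
#' flag `"n/a"`).
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`.
#' @return a data.frame.
#' @export
load_fixture <- function(name) {
  if (!name %in% names(fixture_files))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(fixture_files), collapse = ", "))
  path <- system.file("extdata", fixture_files[[name]],
                      package = "glnregulon", mustWork = TRUE)
  utils::read.delim(path, colClasses = "character", check.names = FALSE)
}

#' Individual consensus sites from the binding-region fixture
#'
#' Splits the semicolon-separated `sites` column of `table3`, dropping the
#' `"n/a"` flags.
#'
#' @param table3 output of `load_fixture("table3")`.
#' @return character vector of full-length site strings.
#' @export
fixture_sites <- function(table3 = load_fixture("table3")) {
  raw <- table3$sites[table3$sites != "n/a"]
  unlist(strsplit(raw, ";", fixed = TRUE), use.names = FALSE)
}
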