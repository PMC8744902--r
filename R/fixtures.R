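#' Packaged fibrosis study tables
#'
#' Returns the published fibrosis protein tables shipped with the package as
#' plain-text fixtures: the 54-row group annotation (4 seed TGF-beta
#' proteins, 20 up-, 20 down-responders and 10 external X-proteins, with
#' local and global rank annotations), the 40 strongest sensitivity pairs,
#' and the 14 per-influencer sums Ds(u/d)(b) with their local PageRank
#' probabilities.  These document the published reference results; they are
#' not reproducible from scratch here because the underlying commercial
#' network database is not redistributable.
#'
#' Two display names appear twice in the source (LAMA1 and IL1R2); they are
#' kept as distinct node ids (`LAMA1_2`, `IL1R2_2`).
#'
#' @return a list with elements `groups` (`protein_groups` data frame,
#'   54 rows), `table2` (40 ranked (a, b, Dab) pairs), `table3` (14 rows of
#'   rank, protein, `Ds_ud`, `Pr`).
#' @export
fibrosis_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "regomax",
                                  mustWork = TRUE)
  groups <- read_group_table(path("fibrosis_groups.tsv"))
  table2 <- utils::read.delim(path("fibrosis_table2.tsv"), sep = "\t",
                              quote = "", stringsAsFactors = FALSE)
  table3 <- utils::read.delim(path("fibrosis_table3.tsv"), sep = "\t",
                              quote = "", stringsAsFactors = FALSE)
  list(groups = groups, table2 = table2, table3 = table3)
}
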