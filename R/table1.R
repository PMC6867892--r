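#' Published brown-rot-unique decay-stage-dependent DEG table
#'
#' The reference list of ortholog groups whose decay-stage-dependent
#' differential expression is unique to the two brown-rot fungi
#' (G. trabeum and P. placenta): early-upregulated entries (including one
#' combined row of 19 ortholog groups with ribosomal-structure functions)
#' and late-upregulated entries, with each species' RPKM and fold change.
#' Shipped as a plain-text fixture in `inst/extdata`.
#'
#' @param path Path to the TSV; defaults to the installed fixture.
#' @return Data frame with columns `stage`, `group_id`, `n_groups`,
#'   `description`, `gtr_rpkm`, `gtr_fc`, `ppl_rpkm`, `ppl_fc`.
#' @export
brown_unique_deg_table <- function(path = system.file(
  "extdata", "table1_brown_unique_degs.tsv", package = "rotshift")) {
  if (!nzchar(path) || !file.exists(path))
    stop("fixture table not found", call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("stage", "group_id", "n_groups") %in% names(tab)))
  tab
}

#' Count brown-rot-unique DEGs in the published table
#'
#' Expands combined rows (e.g. the 19 ribosomal-structure ortholog groups
#' reported as one line) by their `n_groups` multiplicity and counts the
#' ortholog groups per stage and in total.
#'
#' @param tab Output of [brown_unique_deg_table()].
#' @return Named list `early`, `late`, `total`.
#' @export
count_brown_unique_degs <- function(tab = brown_unique_deg_table()) {
  early <- sum(tab$n_groups[tab$stage == "early"])
  late <- sum(tab$n_groups[tab$stage == "late"])
  list(early = early, late = late, total = early + late)
}
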