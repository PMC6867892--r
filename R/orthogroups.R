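#' Ortholog groups from reciprocal best hits
#'
#' Builds ortholog groups from a cross-species similarity table: within each
#' ordered species pair, each gene's best-scoring hit is found (ties broken
#' by lexicographically smallest target, making the result deterministic);
#' reciprocal best hits form edges, and connected components of the
#' resulting graph (single linkage) become groups labelled `MCL_<k>`,
#' numbered by their smallest member gene id. Genes in no reciprocal pair
#' stay out of the table and retain species-specific ids downstream. This
#' RBH + connected-components construction is a deterministic surrogate for
#' Markov-clustering orthology; externally derived ortholog tables in the
#' same (group_id, species, gene_id) layout are accepted anywhere a table
#' from this function is.
#'
#' @param similarity Data frame with columns `species1`, `gene1`,
#'   `species2`, `gene2`, `score` (higher = more similar). Within-species
#'   rows are ignored.
#' @return Data frame `group_id`, `species`, `gene_id`.
#' @export
build_orthogroups_rbh <- function(similarity) {
  req <- c("species1", "gene1", "species2", "gene2", "score")
  if (!all(req %in% names(similarity)))
    stop("similarity table needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  sim <- similarity[similarity$species1 != similarity$species2, , drop = FALSE]
  gene_species <- unique(data.frame(
    gene = c(sim$gene1, sim$gene2),
    species = c(sim$species1, sim$species2),
    stringsAsFactors = FALSE))
  if (anyDuplicated(gene_species$gene))
    stop("duplicate gene ids across species tables", call. = FALSE)

  best_hit <- function(q_sp, t_sp) {
    sub <- rbind(
      stats::setNames(sim[sim$species1 == q_sp & sim$species2 == t_sp,
                          c("gene1", "gene2", "score")],
                      c("query", "target", "score")),
      stats::setNames(sim[sim$species2 == q_sp & sim$species1 == t_sp,
                          c("gene2", "gene1", "score")],
                      c("query", "target", "score")))
    if (!nrow(sub)) return(sub[0, c("query", "target")])
    sub <- sub[order(sub$query, -sub$score, sub$target), , drop = FALSE]
    sub[!duplicated(sub$query), c("query", "target")]
  }

  species <- sort(unique(gene_species$species))
  edges <- NULL
  for (i in seq_along(species)) for (j in seq_along(species)) {
    if (i >= j) next
    fwd <- best_hit(species[i], species[j])
    rev <- best_hit(species[j], species[i])
    recip <- merge(fwd, rev, by.x = c("query", "target"),
                   by.y = c("target", "query"))
    if (nrow(recip))
      edges <- rbind(edges, recip[, c("query", "target")])
  }
  if (is.null(edges) || !nrow(edges))
    return(data.frame(group_id = character(0), species = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))

  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  member <- split(names(comp$membership), comp$membership)
  # deterministic numbering by smallest member gene id
  member <- member[order(vapply(member, min, character(1)))]
  out <- data.frame(
    group_id = rep(sprintf("MCL_%d", seq_along(member)),
                   lengths(member)),
    gene_id = unlist(member, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  out$species <- gene_species$species[match(out$gene_id, gene_species$gene)]
  out <- out[order(as.integer(sub("MCL_", "", out$group_id)), out$species,
                   out$gene_id), c("group_id", "species", "gene_id")]
  rownames(out) <- NULL
  out
}

#' Map per-species stage DEG sets to ortholog-group ids
#'
#' Replaces each gene by its ortholog-group id; genes without an ortholog
#' group keep a species-specific id (`<species>|<gene>`). A group counts as
#' an early (late) DEG of a species when at least one member gene of that
#' species is in the species' early (late) set.
#'
#' @param stage_sets Named list (per species) of lists with `early` and
#'   `late` character vectors of gene ids, as from [pool_stage_sets()].
#' @param orthogroups Table with `group_id`, `species`, `gene_id`.
#' @param annotation Optional gene universe (data frame with `gene_id`);
#'   when given, stage genes absent from it raise an error.
#' @return Named list (per species) of lists with `early` and `late`
#'   character vectors of unique ids.
#' @export
assign_orthodeg_ids <- function(stage_sets, orthogroups, annotation = NULL) {
  lapply(stats::setNames(names(stage_sets), names(stage_sets)),
         function(sp) {
    lapply(stage_sets[[sp]], function(genes) {
      if (!length(genes)) return(character(0))
      if (!is.null(annotation)) {
        absent <- setdiff(genes, annotation$gene_id)
        if (length(absent))
          stop("gene(s) absent from annotation: ",
               paste(utils::head(absent, 3), collapse = ", "),
               call. = FALSE)
      }
      idx <- match(genes, orthogroups$gene_id)
      ids <- ifelse(is.na(idx), paste(sp, genes, sep = "|"),
                    orthogroups$group_id[idx])
      sort(unique(ids))
    })
  })
}
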