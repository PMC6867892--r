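#' Run the full comparative decay-stage pipeline
#'
#' Chains every analysis stage for a multi-species wafer experiment:
#'
#' 1. per species: RPKM normalization, section means, expression evidence,
#'    exact-test differential expression over the three section contrasts,
#'    trend classification and early/late stage pooling;
#' 2. cross-species: ortholog-id mapping of the stage sets, Venn partition
#'    per stage, early-to-late ratio profiles of ortho-DEG groups, Spearman
#'    correlation of samples and hierarchical clustering
#'    (euclidean/complete);
#' 3. functional investment: per-family early/late DEG counts, LOX-shift
#'    Fisher and paired-t tests, GH:LOX transcription ratios and PCA of
#'    family-summed expression.
#'
#' @param counts_list Named list (per species) of [count_matrix()] objects,
#'   e.g. `sim$counts` from [simulate_decay_experiment()].
#' @param design Sample sheet covering all samples (`sample_id`, `species`,
#'   `rot_type`, `section`, `replicate`).
#' @param annotation Gene annotation (`gene_id`, `species`, `family`,
#'   `class`, optionally `go_terms`).
#' @param orthogroups Ortholog table (`group_id`, `species`, `gene_id`).
#' @param dispersion Optional fixed NB dispersion shared by all species;
#'   estimated per species when `NULL`.
#' @param fc_threshold,fdr_threshold DEG thresholds (defaults 4 and 0.05).
#' @param evidence_threshold RPKM threshold for expression evidence.
#' @param eps RPKM pseudocount for the early-to-late ratio.
#' @return Object of class `decay_pipeline` with components `species`
#'   (per-species list: rpkm, section_rpkm, evidence, de, trend,
#'   stage_sets), `ortho_sets`, `venn` (list early/late), `profiles`,
#'   `correlation`, `clustering`, `family_counts`, `shift_tests`,
#'   `investment`, `family_pca`, `rot_type`.
#' @export
#' @examples
#' sim <- simulate_decay_experiment(sim_config(n_orthogroups = 80, seed = 3))
#' res <- run_decay_pipeline(sim$counts, sim$design, sim$annotation,
#'                           sim$orthogroups, dispersion = sim$config$dispersion)
#' res$investment
run_decay_pipeline <- function(counts_list, design, annotation, orthogroups,
                               dispersion = NULL, fc_threshold = 4,
                               fdr_threshold = 0.05,
                               evidence_threshold = 5, eps = 0.1) {
  species <- names(counts_list)
  rot_type <- stats::setNames(
    design$rot_type[match(species, design$species)], species)

  per_species <- list()
  for (sp in species) {
    cm <- counts_list[[sp]]
    d <- design[design$species == sp, , drop = FALSE]
    rpkm <- compute_rpkm(cm)
    sec <- section_means(rpkm, d)
    de <- run_species_de(cm, d, dispersion = dispersion,
                         fc_threshold = fc_threshold,
                         fdr_threshold = fdr_threshold)
    trend <- classify_trend(de)
    per_species[[sp]] <- list(
      rpkm = rpkm,
      section_rpkm = sec,
      evidence = expression_evidence(sec, evidence_threshold),
      de = de,
      trend = trend,
      stage_sets = pool_stage_sets(trend)
    )
  }

  stage_sets <- lapply(per_species, `[[`, "stage_sets")
  ortho_sets <- assign_orthodeg_ids(stage_sets, orthogroups,
                                    annotation = annotation)
  venn <- list(
    early = venn_partition(lapply(ortho_sets, `[[`, "early"), rot_type),
    late = venn_partition(lapply(ortho_sets, `[[`, "late"), rot_type)
  )

  # ortho-DEGs: stage-DEG group ids (MCL ids only) in >= 1 species
  ortho_deg_ids <- sort(unique(grep(
    "^MCL_", unlist(ortho_sets, use.names = FALSE), value = TRUE)))
  rpkm_list <- lapply(per_species, `[[`, "rpkm")
  profiles <- ortho_ratio_profiles(rpkm_list, design, orthogroups,
                                   ids = ortho_deg_ids, eps = eps)
  correlation <- correlation_matrix(profiles, method = "spearman")
  clustering <- NULL
  if (!anyNA(correlation))
    clustering <- hierarchical_cluster(correlation)

  fam_counts <- family_deg_counts(stage_sets, annotation,
                                  rot_type = rot_type)
  shift <- lox_shift_tests(fam_counts)
  sec_list <- lapply(per_species, `[[`, "section_rpkm")
  invest <- investment_ratio(sec_list, annotation)
  fam_expr <- family_expression_matrix(sec_list, annotation)
  fam_pca <- pca_expression(fam_expr)

  structure(list(
    species = per_species,
    ortho_sets = ortho_sets,
    venn = venn,
    profiles = profiles,
    correlation = correlation,
    clustering = clustering,
    family_counts = fam_counts,
    shift_tests = shift,
    investment = invest,
    family_pca = fam_pca,
    rot_type = rot_type
  ), class = "decay_pipeline")
}

#' @export
print.decay_pipeline <- function(x, ...) {
  n_early <- sum(vapply(x$species, function(s) length(s$stage_sets$early),
                        integer(1)))
  n_late <- sum(vapply(x$species, function(s) length(s$stage_sets$late),
                       integer(1)))
  cat(sprintf("decay_pipeline: %d species; %d early / %d late stage DEGs\n",
              length(x$species), n_early, n_late))
  cat(sprintf("  brown-unique ortho-DEGs: %d early, %d late\n",
              length(x$venn$early$brown_unique),
              length(x$venn$late$brown_unique)))
  cat(sprintf("  LOX shift Fisher p = %.3g; paired t p = %.3g\n",
              x$shift_tests$fisher$p, x$shift_tests$paired_t$p))
  invisible(x)
}
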