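#' Generate the sample design of the wafer decay experiment
#'
#' One sample per species x colonized wafer section x biological replicate.
#' The three sections (0-5, 15-20, 30-35 mm behind the hyphal front)
#' represent progressively later decay stages; replicates are labelled
#' A, B, C... The uncolonized "no fungus" section carries no transcriptome
#' and is not simulated.
#'
#' @param config A [sim_config()] object.
#' @return Data frame with columns `sample_id`, `species`, `rot_type`,
#'   `section`, `replicate`; `4 x 3 x 3 = 36` rows at the default design.
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sp <- sim_species(config)
  reps <- if (config$n_replicates <= 26L) LETTERS[seq_len(config$n_replicates)]
          else sprintf("R%04d", seq_len(config$n_replicates))
  design <- expand.grid(
    replicate = reps,
    section = decay_sections(),
    species = sp$species,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )[, c("species", "section", "replicate")]
  design$rot_type <- sp$rot_type[match(design$species, sp$species)]
  design$sample_id <- paste(design$species, design$section, design$replicate,
                            sep = "_")
  rownames(design) <- NULL
  design[, c("sample_id", "species", "rot_type", "section", "replicate")]
}

lox_families <- c("POD", "LPMO", "CRO", "HTP", "FER", "AA3_2", "GLX", "CDH")
gh_families <- c("GH5", "GH3", "GH10", "GH12", "GH28", "GH51", "GH74", "GH27")

#' Generate the synthetic gene catalog: annotation, orthology and truth
#'
#' Seeds `n_orthogroups` ortholog groups, each carrying genes from every
#' species with an inclusion probability calibrated so that the configured
#' fraction of groups is single-copy in all species. Groups are labelled
#' LOX (lignocellulose-oxidizing), GH (glycoside hydrolase) or other, and a
#' fraction of groups per class receives a decay-stage expression program,
#' drawn independently per rot type:
#'
#' * regulated LOX groups are early-upregulated in brown-rot species, while
#'   white-rot species receive LOX effects split between early and late;
#' * regulated GH groups are late-upregulated in both rot types;
#' * regulated "other" groups are assigned early or late at random.
#'
#' Baseline expression additionally shifts transcriptional investment: GH
#' genes are boosted in brown-rot species, LOX genes in white-rot species.
#'
#' @param config A [sim_config()] object.
#' @return List with components `annotation` (gene_id, species, length_bp,
#'   family, class, go_terms), `orthogroups` (group_id, species, gene_id;
#'   groups spanning >= 2 species), and `truth` (per-gene ground truth:
#'   group, class, baseline mean, per-section multipliers, regulated flag
#'   and intended stage).
#' @export
generate_gene_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_orthogroups
  sp <- sim_species(config)
  n_sp <- nrow(sp)

  group_id <- sprintf("MCL_%d", seq_len(G))
  class <- sample(c("LOX", "GH", "other"), G, replace = TRUE,
                  prob = c(config$frac_lox, config$frac_gh,
                           1 - config$frac_lox - config$frac_gh))
  family <- rep(NA_character_, G)
  family[class == "LOX"] <- sample(lox_families, sum(class == "LOX"),
                                   replace = TRUE)
  family[class == "GH"] <- sample(gh_families, sum(class == "GH"),
                                  replace = TRUE)

  # group-level GO terms shared by orthologs
  go_pool <- sprintf("GO:%07d", 1000001:1000020)
  extra_go <- vapply(seq_len(G), function(i) {
    k <- sample(0:2, 1L)
    if (k == 0L) "" else paste(sample(go_pool, k), collapse = ";")
  }, character(1))
  base_go <- ifelse(class == "LOX", "GO:0005506",
                    ifelse(class == "GH", "GO:0004553", ""))
  go_terms <- ifelse(base_go == "", extra_go,
                     ifelse(extra_go == "", base_go,
                            paste(base_go, extra_go, sep = ";")))

  # regulation program per group and rot type
  stage_for <- function(cls, rot) {
    if (cls == "LOX") {
      if (rot == "brown") "early"
      else if (stats::runif(1) < config$white_lox_early_frac) "early"
      else "late"
    } else if (cls == "GH") {
      "late"
    } else {
      sample(c("early", "late"), 1L)
    }
  }
  program <- matrix("none", G, 2L, dimnames = list(NULL, c("brown", "white")))
  for (rot in c("brown", "white")) {
    rate <- rep(config$frac_regulated, G)
    if (rot == "white")
      rate[class == "LOX"] <- config$white_lox_regulated_frac
    reg <- stats::runif(G) < rate
    for (i in which(reg)) program[i, rot] <- stage_for(class[i], rot)
  }

  # membership: copies of each group per species
  copies <- matrix(0L, G, n_sp, dimnames = list(NULL, sp$species))
  for (j in seq_len(n_sp)) {
    inc <- stats::runif(G) < config$p_include
    par <- stats::runif(G) < config$paralog_prob
    copies[, j] <- ifelse(inc, 1L + as.integer(par), 0L)
  }
  # groups absent everywhere get one gene in a random species so every group
  # exists somewhere
  empty <- rowSums(copies) == 0L
  if (any(empty))
    copies[cbind(which(empty), sample.int(n_sp, sum(empty), replace = TRUE))] <- 1L

  rows <- which(copies > 0L, arr.ind = TRUE)
  rows <- rows[order(rows[, 1L], rows[, 2L]), , drop = FALSE]
  n_copy <- copies[rows]
  gi <- rep(rows[, 1L], n_copy)   # group index per gene
  si <- rep(rows[, 2L], n_copy)   # species index per gene

  truth <- data.frame(
    species = sp$species[si],
    rot_type = sp$rot_type[si],
    group_id = group_id[gi],
    class = class[gi],
    family = family[gi],
    stringsAsFactors = FALSE
  )
  # per-species gene numbering, deterministic in group order
  idx <- stats::ave(seq_along(si), si, FUN = seq_along)
  truth$gene_id <- sprintf("%s_g%05d", truth$species, idx)

  n_genes <- nrow(truth)
  truth$length_bp <- as.integer(round(stats::runif(
    n_genes, config$gene_length_range[1], config$gene_length_range[2])))
  lr <- config$baseline_mean_log_range
  truth$baseline <- exp(stats::runif(n_genes, lr[1], lr[2]))
  # transcriptional-investment shift by rot type
  boost <- ifelse(truth$class == "GH" & truth$rot_type == "brown",
                  config$gh_investment_brown,
           ifelse(truth$class == "LOX" & truth$rot_type == "white",
                  config$lox_investment_white, 1))
  truth$baseline <- truth$baseline * boost

  truth$stage <- program[cbind(gi, match(truth$rot_type,
                                         colnames(program)))]
  # a unit multiplier is no effect: the intended stage must reflect the
  # realized mean profile, so effect = 1 demotes the stage to none
  if (config$early_effect == 1) truth$stage[truth$stage == "early"] <- "none"
  if (config$late_effect == 1) truth$stage[truth$stage == "late"] <- "none"
  truth$regulated <- truth$stage != "none"
  truth$mult_early <- ifelse(truth$stage == "early", config$early_effect, 1)
  truth$mult_mid <- ifelse(truth$stage == "late", config$late_effect, 1)
  truth$mult_late <- truth$mult_mid
  truth <- truth[, c("gene_id", "species", "rot_type", "group_id", "class",
                     "family", "length_bp", "baseline", "mult_early",
                     "mult_mid", "mult_late", "regulated", "stage")]

  annotation <- data.frame(
    gene_id = truth$gene_id,
    species = truth$species,
    length_bp = truth$length_bp,
    family = truth$family,
    class = truth$class,
    go_terms = go_terms[gi],
    stringsAsFactors = FALSE
  )

  multi <- tapply(truth$species, truth$group_id,
                  function(s) length(unique(s))) >= 2L
  keep <- truth$group_id %in% names(multi)[multi]
  orthogroups <- data.frame(
    group_id = truth$group_id[keep],
    species = truth$species[keep],
    gene_id = truth$gene_id[keep],
    stringsAsFactors = FALSE
  )
  rownames(orthogroups) <- NULL

  list(annotation = annotation, orthogroups = orthogroups, truth = truth)
}

# NB count draw with variance mu + phi * mu^2 (Poisson at phi = 0)
rnb_counts <- function(mu, phi) {
  if (phi <= 0) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / phi)
}

section_multiplier <- function(truth, section) {
  s <- decay_sections()
  col <- c("mult_early", "mult_mid", "mult_late")[match(section, s)]
  truth[[col]]
}

#' Simulate negative-binomial read counts for the wafer design
#'
#' Counts for gene g in sample s are drawn from a negative binomial with
#' mean `library_size_s * w_gs / sum_g(w_gs)` where
#' `w_gs = baseline_g * section_multiplier_gs * length_g / 1000`, and
#' variance `mu + phi * mu^2` (Poisson when `dispersion = 0`). Realized
#' library sizes are drawn uniformly within +/- 20 percent of the configured
#' depth, so downstream analyses must normalize. A dedicated RNG stream
#' (offset from `config$seed`) keeps counts independent of catalog draws.
#'
#' @param design Output of [generate_design()].
#' @param truth Truth table from [generate_gene_catalog()].
#' @param config A [sim_config()] object.
#' @return Named list (one element per species) of [count_matrix()] objects,
#'   genes x samples.
#' @export
simulate_counts <- function(design, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(design$species %in% truth$species))
    stop("truth does not cover every species in the design", call. = FALSE)
  set.seed(config$seed + 8191L)
  lib <- stats::runif(nrow(design), 0.8, 1.2) * config$library_size

  out <- list()
  for (species in unique(design$species)) {
    tr <- truth[truth$species == species, , drop = FALSE]
    d <- design[design$species == species, , drop = FALSE]
    counts <- matrix(0L, nrow(tr), nrow(d),
                     dimnames = list(tr$gene_id, d$sample_id))
    # fixed reference weights: the library factor is set against the
    # unregulated transcriptome, so section multipliers act literally on
    # each gene's mean rather than being damped by composition
    w_ref <- tr$baseline * tr$length_bp / 1000
    for (k in seq_len(nrow(d))) {
      w <- w_ref * section_multiplier(tr, d$section[k])
      mu <- lib[match(d$sample_id[k], design$sample_id)] * w / sum(w_ref)
      counts[, k] <- rnb_counts(mu, config$dispersion)
    }
    out[[species]] <- count_matrix(counts, stats::setNames(tr$length_bp,
                                                           tr$gene_id))
  }
  out
}

#' Run the full simulation: design, catalog and counts
#'
#' @param config A [sim_config()] object.
#' @return An object of class `decay_sim`: list with `config`, `design`,
#'   `annotation`, `orthogroups`, `truth` and `counts` (per-species
#'   [count_matrix()] list).
#' @export
#' @examples
#' sim <- simulate_decay_experiment(sim_config(n_orthogroups = 60, seed = 7))
#' names(sim$counts)
simulate_decay_experiment <- function(config = sim_config()) {
  design <- generate_design(config)
  catalog <- generate_gene_catalog(config)
  counts <- simulate_counts(design, catalog$truth, config)
  structure(list(config = config, design = design,
                 annotation = catalog$annotation,
                 orthogroups = catalog$orthogroups,
                 truth = catalog$truth, counts = counts),
            class = "decay_sim")
}

#' @export
print.decay_sim <- function(x, ...) {
  cat(sprintf("Simulated decay experiment: %d samples, %d genes, %d species\n",
              nrow(x$design), nrow(x$truth), length(x$counts)))
  invisible(x)
}

#' Write a simulated experiment to plain-text TSV files
#'
#' Emits `samples.tsv`, `annotation.tsv`, `orthogroups.tsv`, `truth.tsv` and
#' one `counts_<species>.tsv` per species (first column `gene_id`).
#'
#' @param sim A `decay_sim` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "decay_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  paths <- c(
    wr(sim$design, "samples.tsv"),
    wr(sim$annotation, "annotation.tsv"),
    wr(sim$orthogroups, "orthogroups.tsv"),
    wr(sim$truth, "truth.tsv")
  )
  for (species in names(sim$counts)) {
    cm <- sim$counts[[species]]
    df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    paths <- c(paths, wr(df, sprintf("counts_%s.tsv", species)))
  }
  invisible(paths)
}

#' Read a count matrix written by [write_simulation()]
#'
#' @param path Path to a counts TSV (first column `gene_id`).
#' @param gene_lengths Named vector of transcript lengths in bp.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, gene_lengths) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  count_matrix(m, gene_lengths[rownames(m)])
}
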