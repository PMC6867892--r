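#' Simulation configuration for the wafer-section decay experiment
#'
#' Defines the conditions under which synthetic multi-species decay-gradient
#' count data are generated: two brown-rot and two white-rot species, three
#' colonized wafer sections, three biological replicates, negative-binomial
#' counts with stage-dependent mean multipliers, and an orthology structure
#' in which most groups carry a single gene from every species.
#'
#' The defaults encode the study design the package targets: 4 species x
#' 3 sections x 3 replicates = 36 libraries; regulated LOX genes in brown-rot
#' species are upregulated at the hyphal front (early), regulated GH genes in
#' later sections (late), while white-rot LOX effects are split between
#' stages with a slight late skew. Brown-rot species put extra baseline
#' transcription into GH genes and white-rot species into LOX genes, so the
#' GH:LOX investment ratio diverges by rot type.
#'
#' @param n_species_brown,n_species_white Number of brown-/white-rot species.
#' @param species_brown,species_white Species labels; defaults are the four
#'   model wood-decay fungi (Ppl, Gtr brown rot; Tve, Pos white rot).
#' @param n_replicates Biological replicates per section, labelled A, B, C...
#' @param n_orthogroups Number of ortholog groups seeding the gene catalogs.
#' @param frac_lox,frac_gh Fraction of orthogroups labelled LOX / GH
#'   (lignocellulose-oxidizing / glycoside hydrolase); must sum to <= 1.
#' @param baseline_mean_log_range Log-scale range (pair) from which per-gene
#'   baseline expression weights are drawn log-uniformly.
#' @param dispersion Negative-binomial dispersion phi >= 0 with
#'   variance = mu + phi * mu^2; 0 gives Poisson counts.
#' @param early_effect Fold multiplier (>= 1) applied at the 0-5 mm section
#'   for early-regulated genes.
#' @param late_effect Fold multiplier (>= 1) applied at the 15-20 and
#'   30-35 mm sections for late-regulated genes.
#' @param frac_regulated Fraction of orthogroups per class given an effect,
#'   drawn independently per rot type.
#' @param white_lox_regulated_frac Fraction of LOX orthogroups given an
#'   effect in white-rot species. White-rot oxidative families are broadly
#'   co-regulated with decay stage (ligninolytic peroxidases, LPMOs and
#'   copper radical oxidases late; laccases and aryl-alcohol oxidases
#'   early), so their regulated fraction exceeds the per-class default.
#' @param library_size Expected mapped reads per sample; realized depths are
#'   drawn uniformly within +/- 20 percent so the pipeline must normalize.
#' @param gene_length_range Transcript length range in bp (pair).
#' @param single_copy_target Target fraction of orthogroups containing
#'   exactly one gene from every species; the per-species inclusion
#'   probability is solved from it in closed form.
#' @param paralog_prob Probability that an included species contributes two
#'   paralogs to a group instead of one.
#' @param gh_investment_brown Baseline fold boost of GH genes in brown-rot
#'   species (transcriptional investment shift).
#' @param lox_investment_white Baseline fold boost of LOX genes in white-rot
#'   species (white-rot fungi divert transcription into oxidative enzymes,
#'   keeping their GH:LOX ratio below 1).
#' @param white_lox_early_frac Probability that a regulated white-rot LOX
#'   group is early- rather than late-upregulated (slight late skew by
#'   default).
#' @param seed Integer seed; fixes every emitted byte of the simulation.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_orthogroups = 50, seed = 1)
#' design <- generate_design(cfg)
#' nrow(design)  # 36 samples
sim_config <- function(n_species_brown = 2L,
                       n_species_white = 2L,
                       species_brown = c("Ppl", "Gtr")[seq_len(n_species_brown)],
                       species_white = c("Tve", "Pos")[seq_len(n_species_white)],
                       n_replicates = 3L,
                       n_orthogroups = 2000L,
                       frac_lox = 0.05,
                       frac_gh = 0.10,
                       baseline_mean_log_range = log(c(10, 1000)),
                       dispersion = 0.05,
                       early_effect = 8,
                       late_effect = 8,
                       frac_regulated = 0.10,
                       white_lox_regulated_frac = 0.25,
                       library_size = 2e5,
                       gene_length_range = c(500L, 3000L),
                       single_copy_target = 0.62,
                       paralog_prob = 0.05,
                       gh_investment_brown = 4,
                       lox_investment_white = 8,
                       white_lox_early_frac = 0.4,
                       seed = 1L) {
  n_species_brown <- as.integer(n_species_brown)
  n_species_white <- as.integer(n_species_white)
  n_species <- n_species_brown + n_species_white
  if (is.na(n_species) || n_species < 1L)
    stop("configuration error: need at least one species", call. = FALSE)
  if (n_species_brown < 0L || n_species_white < 0L)
    stop("configuration error: species counts must be non-negative",
         call. = FALSE)
  if (n_species_brown > 0L &&
      (length(species_brown) != n_species_brown || anyNA(species_brown)))
    stop("configuration error: species_brown labels do not match count",
         call. = FALSE)
  if (n_species_white > 0L &&
      (length(species_white) != n_species_white || anyNA(species_white)))
    stop("configuration error: species_white labels do not match count",
         call. = FALSE)
  if (as.integer(n_replicates) < 1L)
    stop("configuration error: n_replicates must be positive", call. = FALSE)
  if (as.integer(n_orthogroups) < 1L)
    stop("configuration error: n_orthogroups must be positive", call. = FALSE)
  if (frac_lox < 0 || frac_gh < 0 || frac_lox + frac_gh > 1)
    stop("configuration error: frac_lox + frac_gh must lie in [0, 1]",
         call. = FALSE)
  if (dispersion < 0)
    stop("configuration error: dispersion must be >= 0", call. = FALSE)
  if (early_effect < 1 || late_effect < 1)
    stop("configuration error: effects are fold multipliers >= 1",
         call. = FALSE)
  if (frac_regulated < 0 || frac_regulated > 1)
    stop("configuration error: frac_regulated must lie in [0, 1]",
         call. = FALSE)
  if (white_lox_regulated_frac < 0 || white_lox_regulated_frac > 1)
    stop("configuration error: white_lox_regulated_frac must lie in [0, 1]",
         call. = FALSE)
  if (library_size <= 0)
    stop("configuration error: library_size must be positive", call. = FALSE)
  if (length(gene_length_range) != 2L || any(gene_length_range <= 0) ||
      diff(gene_length_range) < 0)
    stop("configuration error: invalid gene_length_range", call. = FALSE)
  if (length(baseline_mean_log_range) != 2L ||
      diff(baseline_mean_log_range) < 0)
    stop("configuration error: invalid baseline_mean_log_range",
         call. = FALSE)
  if (single_copy_target <= 0 || single_copy_target > 1)
    stop("configuration error: single_copy_target must lie in (0, 1]",
         call. = FALSE)
  if (paralog_prob < 0 || paralog_prob >= 1)
    stop("configuration error: paralog_prob must lie in [0, 1)", call. = FALSE)
  if (gh_investment_brown <= 0 || lox_investment_white <= 0)
    stop("configuration error: investment multipliers must be positive",
         call. = FALSE)
  if (white_lox_early_frac < 0 || white_lox_early_frac > 1)
    stop("configuration error: white_lox_early_frac must lie in [0, 1]",
         call. = FALSE)

  # inclusion probability solved so that P(single copy in every species)
  # equals single_copy_target: [p_inc * (1 - paralog_prob)]^n_species = target
  p_single <- single_copy_target^(1 / n_species)
  p_include <- p_single / (1 - paralog_prob)
  if (p_include > 1)
    stop("configuration error: single_copy_target unreachable at this ",
         "paralog_prob", call. = FALSE)

  cfg <- list(
    n_species_brown = n_species_brown,
    n_species_white = n_species_white,
    species_brown = as.character(species_brown),
    species_white = as.character(species_white),
    n_replicates = as.integer(n_replicates),
    n_orthogroups = as.integer(n_orthogroups),
    frac_lox = frac_lox,
    frac_gh = frac_gh,
    baseline_mean_log_range = baseline_mean_log_range,
    dispersion = dispersion,
    early_effect = early_effect,
    late_effect = late_effect,
    frac_regulated = frac_regulated,
    white_lox_regulated_frac = white_lox_regulated_frac,
    library_size = library_size,
    gene_length_range = as.integer(gene_length_range),
    single_copy_target = single_copy_target,
    paralog_prob = paralog_prob,
    p_include = p_include,
    gh_investment_brown = gh_investment_brown,
    lox_investment_white = lox_investment_white,
    white_lox_early_frac = white_lox_early_frac,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Decay-gradient simulation config\n")
  cat(sprintf("  species: %d brown rot (%s), %d white rot (%s)\n",
              x$n_species_brown, paste(x$species_brown, collapse = ", "),
              x$n_species_white, paste(x$species_white, collapse = ", ")))
  cat(sprintf("  %d orthogroups, %d replicates, library size %g\n",
              x$n_orthogroups, x$n_replicates, x$library_size))
  cat(sprintf("  dispersion %.3g, early/late effects %g / %g, %.0f%% regulated\n",
              x$dispersion, x$early_effect, x$late_effect,
              100 * x$frac_regulated))
  invisible(x)
}

sim_species <- function(config) {
  data.frame(
    species = c(config$species_brown, config$species_white),
    rot_type = rep(c("brown", "white"),
                   c(config$n_species_brown, config$n_species_white)),
    stringsAsFactors = FALSE
  )
}
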