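#' Simulation configuration for synthetic FFPE-CUTAC experiments
#'
#' Builds and validates the configuration driving [generate_experiment()].
#' The defaults encode the phenomenology of FFPE-CUTAC data at desk scale:
#' subnucleosomal fragment lengths peaking near 60 bp with a 10-bp
#' periodicity, genotype-dependent median lengths (normal brain 65 bp,
#' tumor 76 bp), enrichment of fragment midpoints at cCRE intervals,
#' non-periodic mitochondrial and contaminant-genome fragments whose share
#' follows an Arrhenius competition model of crosslink reversal, replicate
#' structure with a controlled set of truly changed cCREs, and gene-level
#' RNA-seq counts correlated with cCRE signal.
#'
#' @param seed integer seed; every downstream draw is reproducible given it.
#' @param genome_spec data.frame with columns `contig`, `length`, `role`
#'   (role one of `"nuclear"`, `"mito"`, `"contaminant"`). The default is a
#'   scaled-down genome: one 8-Mb nuclear contig, a 16,299-bp mitochondrial
#'   contig, and a 6.5-Mb aggregate contaminant genome.
#' @param n_ccres number of candidate cis-regulatory elements to place.
#' @param ccre_length_mean mean cCRE length in bp (lengths are exponential);
#'   default 272 bp, the average length of the mouse ENCODE cCRE set.
#' @param genotype_groups character vector of group labels; the first is the
#'   reference (no true effects).
#' @param n_samples_per_group replicates per group.
#' @param fragments_per_sample fragments drawn per sample (all references).
#' @param length_mode mode of the nuclear fragment-length distribution, bp.
#' @param length_spread gamma scale parameter of the length distribution, bp.
#' @param periodicity_period modulation period in bp (default 10).
#' @param periodicity_amplitude modulation depth in `[0, 1)`.
#' @param median_target_by_group named numeric vector of target median
#'   fragment lengths (bp) per group; unnamed groups default to 76 bp
#'   (tumor) and the reference group to 65 bp (normal).
#' @param ccre_enrichment fold-enrichment of fragment-midpoint density
#'   inside cCREs relative to background.
#' @param frac_up_regions,frac_down_regions proportions of cCREs with true
#'   up/down effects in each non-reference group.
#' @param effect_logfc magnitude of the true log2 fold change.
#' @param temperature_series numeric vector of incubation temperatures, degC.
#' @param arrhenius_lnA,arrhenius_EaoverR Arrhenius intercept and activation
#'   temperature Ea/R (Kelvin) for the nuclear recovery rate
#'   `k(T) = exp(lnA - EaoverR / T_Kelvin)`. Defaults are calibrated so that
#'   the nuclear fraction is ~13% at 65-70 degC and ~75% at 90-95 degC.
#' @param contaminant_base_rate competition constant of the unfixed
#'   contaminant DNA; nuclear fraction is `k / (k + contaminant_base_rate)`.
#' @param mito_fraction fraction of the recovered (non-contaminant) material
#'   that is mitochondrial.
#' @param sample_temperature incubation temperature assigned to generated
#'   samples (degC).
#' @param n_genes number of genes in the synthetic transcript table.
#' @param rnaseq_depth expected total RNA-seq counts per sample.
#' @param rnaseq_dispersion negative-binomial dispersion of RNA-seq counts.
#'
#' @return A validated list of class `SimConfig`.
#' @seealso [generate_experiment()], [simulate_temperature_series()]
#' @export
sim_config <- function(seed,
                       genome_spec = default_genome_spec(),
                       n_ccres = 1000L,
                       ccre_length_mean = 272,
                       genotype_groups = c("Normal", "YAP1"),
                       n_samples_per_group = 5L,
                       fragments_per_sample = 100000L,
                       length_mode = 60,
                       length_spread = 8,
                       periodicity_period = 10,
                       periodicity_amplitude = 0.35,
                       median_target_by_group = NULL,
                       ccre_enrichment = 20,
                       frac_up_regions = 0.02,
                       frac_down_regions = 0.001,
                       effect_logfc = 1.5,
                       temperature_series = seq(65, 95, by = 5),
                       arrhenius_lnA = 41.66,
                       arrhenius_EaoverR = 14723,
                       contaminant_base_rate = 1,
                       mito_fraction = 0.03,
                       sample_temperature = 90,
                       n_genes = 120L,
                       rnaseq_depth = 5e5,
                       rnaseq_dispersion = 0.1) {
  if (missing(seed)) stop_field("seed", "a seed is mandatory")
  seed <- suppressWarnings(as.integer(seed))
  if (is.na(seed)) stop_field("seed", "must be coercible to integer")

  if (is.null(median_target_by_group) && length(genotype_groups) >= 1L) {
    median_target_by_group <- stats::setNames(
      c(65, rep(76, length(genotype_groups) - 1L)), genotype_groups)
  }

  cfg <- structure(list(
    seed = seed,
    genome_spec = genome_spec,
    n_ccres = n_ccres,
    ccre_length_mean = ccre_length_mean,
    genotype_groups = genotype_groups,
    n_samples_per_group = n_samples_per_group,
    fragments_per_sample = fragments_per_sample,
    length_mode = length_mode,
    length_spread = length_spread,
    periodicity_period = periodicity_period,
    periodicity_amplitude = periodicity_amplitude,
    median_target_by_group = median_target_by_group,
    ccre_enrichment = ccre_enrichment,
    frac_up_regions = frac_up_regions,
    frac_down_regions = frac_down_regions,
    effect_logfc = effect_logfc,
    temperature_series = temperature_series,
    arrhenius_lnA = arrhenius_lnA,
    arrhenius_EaoverR = arrhenius_EaoverR,
    contaminant_base_rate = contaminant_base_rate,
    mito_fraction = mito_fraction,
    sample_temperature = sample_temperature,
    n_genes = n_genes,
    rnaseq_depth = rnaseq_depth,
    rnaseq_dispersion = rnaseq_dispersion
  ), class = "SimConfig")
  validate_sim_config(cfg)
  cfg
}

#' Default scaled-down genome specification
#' @return data.frame with columns `contig`, `length`, `role`.
#' @export
default_genome_spec <- function() {
  data.frame(
    contig = c("chr1", "chrM", "contam1"),
    length = c(8e6, 16299, 6.5e6),
    role = c("nuclear", "mito", "contaminant"),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  gs <- cfg$genome_spec
  if (!is.data.frame(gs) || !all(c("contig", "length", "role") %in% names(gs)))
    stop_field("genome_spec", "needs columns contig, length, role")
  if (anyDuplicated(gs$contig))
    stop_field("genome_spec", "contig names must be unique")
  if (!all(gs$role %in% c("nuclear", "mito", "contaminant")))
    stop_field("genome_spec", "role must be nuclear, mito or contaminant")
  if (any(gs$length <= 0))
    stop_field("genome_spec", "contig lengths must be positive")
  if (!any(gs$role == "nuclear"))
    stop_field("genome_spec", "at least one nuclear contig is required")
  assert_scalar_count(cfg$n_ccres, "n_ccres")
  assert_scalar_count(cfg$n_samples_per_group, "n_samples_per_group")
  assert_scalar_count(cfg$fragments_per_sample, "fragments_per_sample")
  assert_scalar_count(cfg$n_genes, "n_genes")
  if (length(cfg$genotype_groups) < 1L || !is.character(cfg$genotype_groups))
    stop_field("genotype_groups", "must be a non-empty character vector")
  if (anyDuplicated(cfg$genotype_groups))
    stop_field("genotype_groups", "labels must be unique")
  assert_prob(cfg$periodicity_amplitude, "periodicity_amplitude", open_upper = TRUE)
  assert_prob(cfg$frac_up_regions, "frac_up_regions")
  assert_prob(cfg$frac_down_regions, "frac_down_regions")
  if (cfg$frac_up_regions + cfg$frac_down_regions > 1)
    stop_field("frac_up_regions", "frac_up_regions + frac_down_regions must be <= 1")
  if (cfg$ccre_length_mean <= 0) stop_field("ccre_length_mean", "must be positive")
  if (cfg$length_mode <= 0) stop_field("length_mode", "must be positive")
  if (cfg$length_spread <= 0) stop_field("length_spread", "must be positive")
  if (cfg$periodicity_period <= 0) stop_field("periodicity_period", "must be positive")
  if (cfg$ccre_enrichment < 1) stop_field("ccre_enrichment", "must be >= 1")
  if (length(cfg$temperature_series) < 1L)
    stop_field("temperature_series", "must be non-empty")
  if (any(cfg$temperature_series <= -273.15))
    stop_field("temperature_series", "temperatures must exceed absolute zero")
  if (cfg$contaminant_base_rate < 0)
    stop_field("contaminant_base_rate", "must be non-negative")
  assert_prob(cfg$mito_fraction, "mito_fraction", open_upper = TRUE)
  if (!all(cfg$genotype_groups %in% names(cfg$median_target_by_group)))
    stop_field("median_target_by_group", "every genotype group needs a target median")
  if (cfg$rnaseq_dispersion <= 0) stop_field("rnaseq_dispersion", "must be positive")
  if (cfg$rnaseq_depth <= 0) stop_field("rnaseq_depth", "must be positive")
  invisible(cfg)
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig (seed ", x$seed, ")\n", sep = "")
  cat("  genome: ", paste(sprintf("%s[%s,%g]", x$genome_spec$contig,
                                  x$genome_spec$role, x$genome_spec$length),
                          collapse = " "), "\n", sep = "")
  cat("  groups: ", paste(x$genotype_groups, collapse = ", "),
      " x ", x$n_samples_per_group, " replicates\n", sep = "")
  cat("  fragments/sample: ", x$fragments_per_sample,
      ", cCREs: ", x$n_ccres, "\n", sep = "")
  invisible(x)
}
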