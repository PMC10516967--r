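#' Discrete fragment-length probability mass function
#'
#' Gamma base distribution re-parameterized by mode and spread (scale),
#' truncated to `[25, 400]` bp, with an optional cosine modulation
#' `1 + a * cos(2*pi*L / period)` producing the 10-bp periodicity typical
#' of tagmentation within chromatin.
#'
#' @param mode mode of the gamma base distribution, bp.
#' @param spread gamma scale parameter, bp.
#' @param amplitude modulation depth in `[0, 1)`.
#' @param period modulation period, bp.
#' @param support integer lengths over which the pmf is defined.
#' @return data.frame with columns `length` and `prob` (sums to 1).
#' @keywords internal
length_pmf <- function(mode, spread, amplitude = 0, period = 10,
                       support = 25:400) {
  shape <- mode / spread + 1
  dens <- stats::dgamma(support, shape = shape, scale = spread)
  dens <- dens * (1 + amplitude * cos(2 * pi * support / period))
  data.frame(length = support, prob = dens / sum(dens))
}

pmf_median_cont <- function(pmf) {
  cdf <- cumsum(pmf$prob)
  i <- which(cdf >= 0.5)[1]
  lo <- if (i == 1) 0 else cdf[i - 1]
  pmf$length[i] - 1 + (0.5 - lo) / (cdf[i] - lo)
}

#' Solve for the gamma mode hitting a target median length
#'
#' Adjusts the mode of [length_pmf()] (spread, truncation and modulation
#' fixed) so that the continuous median of the discrete pmf equals the
#' target; used to meet per-group median targets (e.g. normal 65 bp,
#' tumor 76 bp).
#' @keywords internal
calibrate_length_mode <- function(target_median, spread, amplitude, period) {
  f <- function(m) pmf_median_cont(length_pmf(m, spread, amplitude, period)) -
    target_median
  stats::uniroot(f, lower = 26, upper = 300, tol = 1e-4)$root
}

sample_lengths <- function(n, pmf) {
  sample(pmf$length, n, replace = TRUE, prob = pmf$prob)
}

#' Expected per-reference fragment fractions at a temperature
#'
#' Nuclear recovery follows an Arrhenius rate `k(T) = exp(lnA - EaoverR/T)`
#' (T in Kelvin) competing against unfixed contaminant DNA with constant
#' rate `contaminant_base_rate`; the nuclear share of recovered material is
#' `k / (k + c)`, of which `mito_fraction` is mitochondrial.
#' @keywords internal
expected_fractions <- function(config, temperature) {
  if (any(temperature <= -273.15))
    stop("temperature must exceed absolute zero (-273.15 degC)", call. = FALSE)
  Tk <- temperature + 273.15
  k <- exp(config$arrhenius_lnA - config$arrhenius_EaoverR / Tk)
  f <- k / (k + config$contaminant_base_rate)
  data.frame(temperature = temperature,
             nuclear = f * (1 - config$mito_fraction),
             mito = f * config$mito_fraction,
             contaminant = 1 - f)
}

#' Arrhenius temperature series of nuclear vs contaminant recovery
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per temperature in
#'   `config$temperature_series`: `temperature` (degC), `nuclear_fraction`
#'   (fraction of fragments mapping to the nuclear reference, including
#'   its mitochondrial share) and `contaminant_fraction`. The nuclear
#'   fraction is non-decreasing in temperature; with
#'   `contaminant_base_rate = 0` it is 1 at every temperature.
#' @export
simulate_temperature_series <- function(config) {
  if (length(config$temperature_series) == 0)
    stop("temperature_series is empty", call. = FALSE)
  ef <- expected_fractions(config, config$temperature_series)
  data.frame(temperature = ef$temperature,
             nuclear_fraction = ef$nuclear + ef$mito,
             contaminant_fraction = ef$contaminant)
}

#' Simulate noisy per-sample contamination profiles over a temperature series
#'
#' Draws `n_per_temp` samples at each temperature of the config's series;
#' multiplicative log-normal noise (sd `noise_sd`) perturbs the Arrhenius
#' recovery rate, and a small uniform unassigned remainder is carved out of
#' the contaminant share, emulating reads mapping to none of the
#' references.
#'
#' @param config a [sim_config()].
#' @param n_per_temp samples per temperature.
#' @param noise_sd sd of the noise on the log recovery rate.
#' @param seed integer seed.
#' @return data.frame of class `ContaminationProfile` with columns
#'   `sample`, `temperature`, `nuclear`, `mito`, `contaminant`,
#'   `unassigned` (rows sum to 1).
#' @export
simulate_contamination_profiles <- function(config, n_per_temp = 3,
                                            noise_sd = 0.05,
                                            seed = config$seed) {
  temps <- rep(config$temperature_series, each = n_per_temp)
  with_seed(seed, {
    Tk <- temps + 273.15
    k <- exp(config$arrhenius_lnA - config$arrhenius_EaoverR / Tk +
               stats::rnorm(length(Tk), 0, noise_sd))
    f <- k / (k + config$contaminant_base_rate)
    u <- (1 - f) * stats::runif(length(f), 0, 0.1)
    out <- data.frame(
      sample = sprintf("T%g_rep%d", temps,
                       sequence(rep(n_per_temp, length(config$temperature_series)))),
      temperature = temps,
      nuclear = f * (1 - config$mito_fraction),
      mito = f * config$mito_fraction,
      contaminant = 1 - f - u,
      unassigned = u)
    class(out) <- c("ContaminationProfile", "data.frame")
    out
  })
}

place_ccres <- function(config) {
  nuc <- config$genome_spec[config$genome_spec$role == "nuclear", , drop = FALSE]
  lens <- pmax(50L, as.integer(round(stats::rexp(config$n_ccres,
                                                 1 / config$ccre_length_mean))))
  # proportional allocation of elements to nuclear contigs, then uniform
  # non-overlapping placement by sorting random starts and rejecting clashes
  ctg_idx <- sample.int(nrow(nuc), config$n_ccres, replace = TRUE,
                        prob = nuc$length)
  out <- vector("list", nrow(nuc))
  for (i in seq_len(nrow(nuc))) {
    li <- lens[ctg_idx == i]
    if (!length(li)) next
    L <- nuc$length[i]
    starts <- integer(0)
    ends <- integer(0)
    for (l in li) {
      for (try in 1:200) {
        s <- sample.int(L - l, 1L) - 1L
        if (!length(starts) || all(s + l <= starts | s >= ends)) {
          starts <- c(starts, s); ends <- c(ends, s + l)
          break
        }
      }
    }
    o <- order(starts)
    out[[i]] <- data.frame(contig = nuc$contig[i], start = starts[o],
                           end = ends[o], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df$id <- sprintf("cCRE_%05d", seq_len(nrow(df)))
  region_set(df)
}

make_truth_regions <- function(config, ccres) {
  groups <- config$genotype_groups
  n <- nrow(ccres)
  n_up <- round(config$frac_up_regions * n)
  n_down <- round(config$frac_down_regions * n)
  out <- lapply(groups, function(g) {
    dir <- rep("null", n)
    eff <- rep(0, n)
    if (g != groups[1] && (n_up + n_down) > 0) {
      pick <- sample.int(n, n_up + n_down)
      if (n_up > 0) {
        dir[pick[seq_len(n_up)]] <- "up"
        eff[pick[seq_len(n_up)]] <- config$effect_logfc
      }
      if (n_down > 0) {
        dir[pick[n_up + seq_len(n_down)]] <- "down"
        eff[pick[n_up + seq_len(n_down)]] <- -config$effect_logfc
      }
    }
    data.frame(region_id = ccres$id, group = g, true_logfc = eff,
               direction = dir, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

make_transcripts <- function(config) {
  nuc <- config$genome_spec[config$genome_spec$role == "nuclear", , drop = FALSE]
  n <- config$n_genes
  ctg_idx <- sample.int(nrow(nuc), n, replace = TRUE, prob = nuc$length)
  span <- pmax(2000L, as.integer(round(stats::rexp(n, 1 / 20000))))
  rows <- lapply(seq_len(n), function(i) {
    L <- nuc$length[ctg_idx[i]]
    s <- sample.int(max(1L, L - span[i]), 1L) - 1L
    ntx <- sample(1:3, 1L)
    tx_s <- s + as.integer(stats::runif(ntx, 0, span[i] * 0.3))
    tx_e <- s + span[i] - as.integer(stats::runif(ntx, 0, span[i] * 0.3))
    tx_e <- pmax(tx_e, tx_s + 100L)
    data.frame(gene = sprintf("gene_%04d", i), contig = nuc$contig[ctg_idx[i]],
               strand = sample(c("+", "-"), 1L),
               txStart = tx_s, txEnd = pmin(tx_e, L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

sample_nuclear_fragments <- function(config, n, group, ccres, ccre_weight,
                                     truth_g, pmf) {
  nuc <- config$genome_spec[config$genome_spec$role == "nuclear", , drop = FALSE]
  Gn <- sum(as.numeric(nuc$length))
  C <- sum(ccres$end - ccres$start)
  E <- config$ccre_enrichment
  # the enriched channel carries only the excess density above the uniform
  # background, so E = 1 degenerates to a fully uniform sample
  p_in <- ((E - 1) * C) / ((E - 1) * C + Gn)
  in_ccre <- stats::runif(n) < p_in
  n_in <- sum(in_ccre)
  mids <- numeric(n)
  ctg <- character(n)
  if (n_in > 0) {
    w <- ccre_weight * (ccres$end - ccres$start) * 2^truth_g$true_logfc
    j <- sample.int(nrow(ccres), n_in, replace = TRUE, prob = w)
    mids[in_ccre] <- ccres$start[j] +
      stats::runif(n_in) * (ccres$end[j] - ccres$start[j])
    ctg[in_ccre] <- ccres$contig[j]
  }
  n_bg <- n - n_in
  if (n_bg > 0) {
    ci <- sample.int(nrow(nuc), n_bg, replace = TRUE, prob = nuc$length)
    mids[!in_ccre] <- stats::runif(n_bg) * nuc$length[ci]
    ctg[!in_ccre] <- nuc$contig[ci]
  }
  len <- sample_lengths(n, pmf)
  L <- stats::setNames(nuc$length, nuc$contig)[ctg]
  start <- pmin(pmax(0, round(mids - len / 2)), L - len)
  data.frame(contig = ctg, start = as.integer(start),
             end = as.integer(start + len), reference = "nuclear",
             stringsAsFactors = FALSE)
}

sample_uniform_fragments <- function(config, n, role, pmf) {
  sp <- config$genome_spec[config$genome_spec$role == role, , drop = FALSE]
  if (nrow(sp) == 0 || n == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), reference = character(0),
                      stringsAsFactors = FALSE))
  ci <- sample.int(nrow(sp), n, replace = TRUE, prob = sp$length)
  len <- sample_lengths(n, pmf)
  len <- pmin(len, sp$length[ci])
  start <- floor(stats::runif(n) * (sp$length[ci] - len + 1))
  data.frame(contig = sp$contig[ci], start = as.integer(start),
             end = as.integer(start + len), reference = role,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic FFPE-CUTAC experiment
#'
#' Draws, for each sample, a mixture of nuclear, mitochondrial and
#' contaminant-genome fragments. Nuclear fragment lengths follow a
#' truncated gamma distribution modulated by
#' `1 + a * cos(2*pi*L/period)`; per-group gamma modes are calibrated so
#' realized medians land within ~2 bp of `median_target_by_group` for
#' 50,000+ fragments. Fragment midpoints fall inside cCREs with
#' probability proportional to `ccre_enrichment` (with per-cCRE intensity
#' weights and true group effects), else uniformly. Mitochondrial and
#' contaminant fragments are placed uniformly with no length periodicity.
#' Gene-level RNA-seq counts are negative-binomial with log-mean tied to
#' the summed intensity of cCREs inside each gene, so accessibility and
#' expression are correlated across genes and share true effects.
#'
#' @param config a [sim_config()].
#' @return list with elements `fragments` (list of [fragment_set()], one
#'   per sample), `ccres` (a [region_set()]), `transcripts` (refGene-like
#'   data.frame), `sample_sheet` (data.frame: sample, antibody, genotype,
#'   temperature), `rnaseq` (genes x samples count matrix), and `truth`
#'   (list `regions` / `samples`).
#' @export
generate_experiment <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    ccres <- place_ccres(config)
    ccre_weight <- stats::rlnorm(nrow(ccres), 0, 1)
    truth_regions <- make_truth_regions(config, ccres)
    transcripts <- make_transcripts(config)
    groups <- config$genotype_groups

    modes <- vapply(groups, function(g)
      calibrate_length_mode(config$median_target_by_group[[g]],
                            config$length_spread,
                            config$periodicity_amplitude,
                            config$periodicity_period), 0)
    pmfs <- lapply(modes, function(m)
      length_pmf(m, config$length_spread, config$periodicity_amplitude,
                 config$periodicity_period))
    names(pmfs) <- groups
    pmf_flat <- length_pmf(config$length_mode, config$length_spread, 0,
                           config$periodicity_period)

    sheet <- expand.grid(rep = seq_len(config$n_samples_per_group),
                         genotype = groups, stringsAsFactors = FALSE)
    sheet <- data.frame(sample = sprintf("%s_rep%d", sheet$genotype, sheet$rep),
                        antibody = "RNAPII-Ser5p",
                        genotype = sheet$genotype,
                        temperature = config$sample_temperature,
                        stringsAsFactors = FALSE)

    ef <- expected_fractions(config, config$sample_temperature)
    frac <- c(nuclear = ef$nuclear, mito = ef$mito, contaminant = ef$contaminant)
    has_mito <- any(config$genome_spec$role == "mito")
    has_cont <- any(config$genome_spec$role == "contaminant")
    if (!has_mito) { frac["nuclear"] <- frac["nuclear"] + frac["mito"]; frac["mito"] <- 0 }
    if (!has_cont) { frac["contaminant"] <- 0; frac <- frac / sum(frac) }

    fragments <- vector("list", nrow(sheet))
    names(fragments) <- sheet$sample
    for (i in seq_len(nrow(sheet))) {
      g <- sheet$genotype[i]
      counts <- as.vector(stats::rmultinom(1, config$fragments_per_sample, frac))
      names(counts) <- names(frac)
      tg <- truth_regions[truth_regions$group == g, ]
      nucf <- sample_nuclear_fragments(config, counts["nuclear"], g, ccres,
                                       ccre_weight, tg, pmfs[[g]])
      mitof <- sample_uniform_fragments(config, counts["mito"], "mito", pmf_flat)
      contf <- sample_uniform_fragments(config, counts["contaminant"],
                                        "contaminant", pmf_flat)
      fragments[[i]] <- fragment_set(
        rbind(nucf, mitof, contf), sample_id = sheet$sample[i],
        metadata = list(antibody = sheet$antibody[i], genotype = g,
                        temperature = sheet$temperature[i]))
    }

    # gene latent signal = summed intensity of cCREs whose midpoint lies in
    # the winnowed gene span, sharing the group's true effects
    genes <- winnow_genes(transcripts)
    mid <- (ccres$start + ccres$end) / 2
    rnaseq <- matrix(0L, nrow = nrow(genes), ncol = nrow(sheet),
                     dimnames = list(genes$id, sheet$sample))
    for (i in seq_len(nrow(sheet))) {
      g <- sheet$genotype[i]
      tg <- truth_regions[truth_regions$group == g, ]
      w <- ccre_weight * 2^tg$true_logfc
      sig <- vapply(seq_len(nrow(genes)), function(k) {
        inside <- ccres$contig == genes$contig[k] &
          mid >= genes$start[k] & mid < genes$end[k]
        sum(w[inside])
      }, 0)
      lat <- sig + 0.1
      mu <- config$rnaseq_depth * lat * exp(stats::rnorm(nrow(genes), 0, 0.1)) /
        sum(lat)
      rnaseq[, i] <- stats::rnbinom(nrow(genes), mu = mu,
                                    size = 1 / config$rnaseq_dispersion)
    }

    truth_samples <- cbind(sheet[, c("sample", "genotype", "temperature")],
                           expected_nuclear = frac[["nuclear"]],
                           expected_mito = frac[["mito"]],
                           expected_contaminant = frac[["contaminant"]])

    list(fragments = fragments, ccres = ccres, transcripts = transcripts,
         sample_sheet = sheet, rnaseq = rnaseq,
         truth = list(regions = truth_regions, samples = truth_samples))
  })
}

#' Simulate a region-by-sample quantification matrix directly
#'
#' Matrix-level counterpart of the fragment generator, used to calibrate
#' and stress the differential module at sizes (thousands of regions,
#' hundreds of replicate simulations) where fragment-level generation is
#' unnecessary. Values emulate per-region sums of normalized counts:
#' `2^(mu_r + effect + N(0, sigma_r))` with region baselines
#' `mu_r ~ N(8, 1.7)` on the log2 scale.
#'
#' @param n_regions number of regions.
#' @param groups character vector of group labels (first = reference).
#' @param n_per_group replicates per group.
#' @param frac_up,frac_down proportions of regions with true up/down
#'   effects in non-reference groups.
#' @param effect_logfc magnitude of the true log2 effect.
#' @param sigma_log2 replicate noise sd on the log2 scale.
#' @param sigma_het relative half-width of per-region sd heterogeneity:
#'   region sds are uniform on `sigma_log2 * (1 +/- sigma_het)`.
#' @param seed integer seed.
#' @return list with `matrix` (regions x samples), `groups` (factor per
#'   sample) and `truth` (data.frame region_id, true_logfc, direction for
#'   each non-reference group).
#' @export
simulate_quant_matrix <- function(n_regions, groups = c("A", "B"),
                                  n_per_group = 5, frac_up = 0,
                                  frac_down = 0, effect_logfc = 0,
                                  sigma_log2 = 0.3, sigma_het = 0,
                                  seed = 1) {
  with_seed(seed, {
    samples <- paste0(rep(groups, each = n_per_group), "_rep",
                      rep(seq_len(n_per_group), length(groups)))
    gvec <- factor(rep(groups, each = n_per_group), levels = groups)
    mu <- stats::rnorm(n_regions, 8, 1.7)
    sds <- sigma_log2 * stats::runif(n_regions, 1 - sigma_het, 1 + sigma_het)
    eff <- matrix(0, n_regions, length(groups),
                  dimnames = list(NULL, groups))
    n_up <- round(frac_up * n_regions)
    n_down <- round(frac_down * n_regions)
    truth <- NULL
    for (g in groups[-1]) {
      d <- rep("null", n_regions)
      if (n_up + n_down > 0) {
        pick <- sample.int(n_regions, n_up + n_down)
        if (n_up > 0) { eff[pick[seq_len(n_up)], g] <- effect_logfc
                        d[pick[seq_len(n_up)]] <- "up" }
        if (n_down > 0) { eff[pick[n_up + seq_len(n_down)], g] <- -effect_logfc
                          d[pick[n_up + seq_len(n_down)]] <- "down" }
      }
      truth <- rbind(truth, data.frame(
        region_id = sprintf("region_%05d", seq_len(n_regions)), group = g,
        true_logfc = eff[, g], direction = d, stringsAsFactors = FALSE))
    }
    m <- matrix(0, n_regions, length(samples),
                dimnames = list(sprintf("region_%05d", seq_len(n_regions)),
                                samples))
    for (j in seq_along(samples)) {
      m[, j] <- 2^(mu + eff[, as.character(gvec[j])] +
                     stats::rnorm(n_regions, 0, sds))
    }
    list(matrix = m, groups = gvec, truth = truth)
  })
}

#' Write all parts of a synthetic experiment to a directory
#'
#' Fragment sets go to BED3+ (`<sample>.fragments.bed`), cCREs and
#' winnowed genes to BED, the sample sheet to CSV, RNA-seq counts and
#' truth tables to TSV, and chrom.sizes per the genome spec.
#'
#' @param experiment result of [generate_experiment()].
#' @param config the [sim_config()] used.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cs <- data.frame(contig = config$genome_spec$contig,
                   size = config$genome_spec$length)
  write_chrom_sizes(cs, file.path(dir, "genome.chrom.sizes"))
  for (s in names(experiment$fragments))
    write_fragments(experiment$fragments[[s]],
                    file.path(dir, paste0(s, ".fragments.bed")))
  write_regions(experiment$ccres, file.path(dir, "ccres.bed"))
  utils::write.table(experiment$transcripts, file.path(dir, "transcripts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(experiment$sample_sheet, file.path(dir, "sample_sheet.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(gene = rownames(experiment$rnaseq),
                                experiment$rnaseq, check.names = FALSE),
                     file.path(dir, "rnaseq_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(experiment$truth$regions,
                     file.path(dir, "truth_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(experiment$truth$samples,
                     file.path(dir, "truth_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
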