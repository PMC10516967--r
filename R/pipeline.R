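#' Read a pipeline configuration file
#'
#' YAML (or JSON-compatible YAML) with either a `simulate:` block of
#' [sim_config()] fields or a `paths:` block pointing at real inputs
#' (fragments, chrom_sizes, ccres, transcripts, rnaseq, sample_sheet),
#' plus optional stage parameter blocks (`peaks`, `depths`, `contrasts`,
#' `fdr_alpha`, `pseudocount`) and `out_dir`.
#'
#' @param path YAML file.
#' @return list of class `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_pipeline_config(cfg)
}

#' Coerce a list to a PipelineConfig
#' @param cfg named list, see [read_pipeline_config()].
#' @return list of class `PipelineConfig`.
#' @export
as_pipeline_config <- function(cfg) {
  has_sim <- !is.null(cfg$simulate)
  has_paths <- !is.null(cfg$paths)
  if (has_sim == has_paths)
    stop("config must provide exactly one of 'simulate' or 'paths'",
         call. = FALSE)
  if (is.null(cfg$seed) && has_sim && is.null(cfg$simulate$seed))
    stop("a seed is mandatory", call. = FALSE)
  structure(cfg, class = c("PipelineConfig", "list"))
}

pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    if (!is.null(sim_args$genome_spec))
      sim_args$genome_spec <- as.data.frame(sim_args$genome_spec)
    sc <- do.call(sim_config, sim_args)
    exp <- generate_experiment(sc)
    chrom_sizes <- data.frame(contig = sc$genome_spec$contig,
                              size = sc$genome_spec$length)
    list(sim_config = sc, chrom_sizes = chrom_sizes,
         fragments = exp$fragments, ccres = exp$ccres,
         transcripts = exp$transcripts, sample_sheet = exp$sample_sheet,
         rnaseq = exp$rnaseq, truth = exp$truth)
  } else {
    p <- config$paths
    chrom_sizes <- read_chrom_sizes(p$chrom_sizes)
    sheet <- utils::read.csv(p$sample_sheet, stringsAsFactors = FALSE)
    frags <- lapply(seq_len(nrow(sheet)), function(i) {
      read_fragments(file.path(p$fragments, paste0(sheet$sample[i],
                                                   ".fragments.bed")),
                     chrom_sizes, sample_id = sheet$sample[i],
                     metadata = list(antibody = sheet$antibody[i],
                                     genotype = sheet$genotype[i],
                                     temperature = sheet$temperature[i]))
    })
    names(frags) <- sheet$sample
    rnaseq <- NULL
    if (!is.null(p$rnaseq)) {
      rn <- utils::read.table(p$rnaseq, sep = "\t", header = TRUE,
                              check.names = FALSE)
      rnaseq <- as.matrix(rn[, -1, drop = FALSE])
      rownames(rnaseq) <- rn[[1]]
    }
    list(sim_config = NULL, chrom_sizes = chrom_sizes, fragments = frags,
         ccres = read_regions(p$ccres),
         transcripts = read_transcripts(p$transcripts),
         sample_sheet = sheet, rnaseq = rnaseq, truth = NULL)
  }
}

stage_header <- function(con, stage, config) {
  writeLines(sprintf("# stage: %s | seed: %s | ffpecutac %s", stage,
                     config$seed %||% "NA",
                     as.character(utils::packageVersion("ffpecutac"))), con)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> coverage tracks -> fragment-length
#' analytics -> peak/FRiP downsampling benchmark -> cCRE and gene
#' quantification -> empirical-Bayes differential comparisons ->
#' contamination/Arrhenius analysis, writing each stage's outputs as
#' self-describing TSV/BED files under `out_dir`. Re-running with the
#' same config and seed reproduces identical outputs.
#'
#' @param config a `PipelineConfig` ([read_pipeline_config()] /
#'   [as_pipeline_config()]) or a path to a YAML config.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param quiet suppress progress messages to stderr.
#' @return (invisibly) a report list with the per-stage objects:
#'   `benchmark`, `quant` (QuantMatrix), `diff` (list of DiffResult),
#'   `lengths`, `periodicity`, `profiles`, `arrhenius`, `rank_curves`,
#'   `sample_sheet`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "PipelineConfig")) config <- as_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("out_dir required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% config$simulate$seed
  say <- function(...) if (!quiet) message("[ffpecutac] ", ...)

  say("stage: inputs")
  inp <- pipeline_inputs(config)
  sheet <- inp$sample_sheet
  missing_groups <- setdiff(unlist(config$contrasts), sheet$genotype)
  if (length(missing_groups))
    stop("stage diff: contrast group(s) absent from sample sheet: ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  if (!is.null(inp$sim_config)) write_experiment(inp[-1], inp$sim_config,
                                                 file.path(out_dir, "simulated"))
  nuc_sizes <- if (!is.null(inp$sim_config)) {
    gs <- inp$sim_config$genome_spec
    data.frame(contig = gs$contig[gs$role == "nuclear"],
               size = gs$length[gs$role == "nuclear"])
  } else {
    ctgs <- unique(inp$ccres$contig)
    inp$chrom_sizes[inp$chrom_sizes$contig %in% ctgs, , drop = FALSE]
  }

  say("stage: tracks")
  tracks <- lapply(inp$fragments, function(fs) {
    nuc <- fs[fs$reference == "nuclear" | !fs$reference %in% c("mito", "contaminant"), ]
    make_track(fragment_set(nuc, sample_id = attr(fs, "sample_id"),
                            metadata = attr(fs, "metadata")), nuc_sizes)
  })
  for (s in names(tracks))
    write_bedgraph(tracks[[s]], file.path(out_dir, paste0(s, ".bedgraph")))

  say("stage: lengths")
  dists <- lapply(inp$fragments, function(fs)
    length_distribution(remove_reference(remove_reference(fs, "mito"),
                                         "contaminant")))
  avg <- average_distributions(dists)
  write_stage_tsv(avg, file.path(out_dir, "length_distribution_mean.tsv"),
                  "lengths", config)
  periodicity <- lapply(dists, periodicity_score)
  per_df <- data.frame(sample = names(dists),
                       median_bp = vapply(dists, `[[`, 0, "median"),
                       periodicity_score = vapply(periodicity, `[[`, 0, "score"),
                       dominant_period = vapply(periodicity, `[[`, 0,
                                                "dominant_period"))
  write_stage_tsv(per_df, file.path(out_dir, "fragment_length_summary.tsv"),
                  "lengths", config)

  say("stage: benchmark")
  depths <- unlist(config$depths %||% c(10000, 50000, 100000))
  bench <- downsampling_benchmark(inp$fragments[[1]], nuc_sizes,
                                  depths[depths <= nrow(inp$fragments[[1]])],
                                  seed = seed,
                                  params = do.call(peak_params,
                                                   config$peaks %||% list()))
  write_stage_tsv(as.data.frame(bench),
                  file.path(out_dir, "benchmark_curve.tsv"), "benchmark", config)

  say("stage: quant")
  qm <- build_quant_matrix(tracks, inp$ccres,
                           mode = config$quant_mode %||% "sum")
  write_quant_matrix(qm, file.path(out_dir, "ccre_quant.tsv"))
  genes <- winnow_genes(inp$transcripts)
  write_regions(genes, file.path(out_dir, "winnowed_genes.bed"))
  gene_qm <- build_quant_matrix(tracks, genes,
                                mode = config$quant_mode %||% "sum")
  write_quant_matrix(gene_qm, file.path(out_dir, "gene_quant.tsv"))
  curves <- lapply(names(tracks), function(s) rank_curve(qm[, s]))
  names(curves) <- names(tracks)
  write_stage_tsv(curves[[1]], file.path(out_dir, "rank_curve_sample1.tsv"),
                  "quant", config)

  say("stage: diff")
  contrasts <- config$contrasts %||% {
    gps <- unique(sheet$genotype)
    if (length(gps) >= 2) lapply(gps[-1], function(g) c(g, gps[1])) else list()
  }
  lc <- log_cpm(qm)
  w <- voom_weights(lc$logged, sheet$genotype)
  diffs <- lapply(contrasts, function(ct) {
    res <- moderated_test(lc$logged, sheet$genotype, ct, weights = w)
    write_diff_result(res, file.path(out_dir,
                                     sprintf("diff_%s_vs_%s.tsv", ct[1], ct[2])))
    res
  })
  names(diffs) <- vapply(contrasts, paste, "", collapse = "_vs_")

  say("stage: contam")
  profiles <- reference_fractions(inp$fragments)
  write_profiles(profiles, file.path(out_dir, "contamination_profiles.tsv"))
  arr <- NULL
  if (!is.null(inp$sim_config)) {
    series <- simulate_temperature_series(inp$sim_config)
    arr <- fit_arrhenius(series$temperature, series$nuclear_fraction,
                         transform = "logit")
    write_stage_tsv(series, file.path(out_dir, "temperature_series.tsv"),
                    "contam", config)
  }

  say("stage: report")
  top <- do.call(rbind, lapply(names(diffs), function(nm) {
    d <- diffs[[nm]]
    d <- d[order(d$fdr), ][seq_len(min(10, nrow(d))), ]
    cbind(contrast = nm, d[, c("region_id", "logfc", "p_value", "fdr")])
  }))
  write_stage_tsv(top, file.path(out_dir, "top_differential_regions.tsv"),
                  "report", config)

  invisible(list(benchmark = bench, quant = qm, gene_quant = gene_qm,
                 diff = diffs, lengths = per_df, length_mean = avg,
                 periodicity = periodicity, profiles = profiles,
                 arrhenius = arr, rank_curves = curves,
                 sample_sheet = sheet, truth = inp$truth))
}

write_stage_tsv <- function(df, path, stage, config) {
  con <- file(path, "w")
  on.exit(close(con))
  stage_header(con, stage, config)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
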