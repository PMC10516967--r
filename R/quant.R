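#' Winnow a transcript table to one region per gene
#'
#' Collapses a refGene-like table (multiple transcripts per gene) to the
#' region from the minimum transcript start to the maximum transcript end
#' for each gene. A gene name appearing on two contigs yields per-contig
#' regions with contig-suffixed ids and a warning.
#'
#' @param transcripts data.frame with columns `gene`, `contig`, `txStart`,
#'   `txEnd` (0-based half-open after ingestion).
#' @return a [region_set()] with ids equal to gene names (suffixed with
#'   `@contig` for multi-contig genes).
#' @export
winnow_genes <- function(transcripts) {
  need <- c("gene", "contig", "txStart", "txEnd")
  if (!all(need %in% names(transcripts)))
    stop("transcript table needs columns gene, contig, txStart, txEnd",
         call. = FALSE)
  key <- paste(transcripts$gene, transcripts$contig, sep = "\r")
  start <- tapply(transcripts$txStart, key, min)
  end <- tapply(transcripts$txEnd, key, max)
  parts <- do.call(rbind, strsplit(names(start), "\r", fixed = TRUE))
  df <- data.frame(contig = parts[, 2], start = as.integer(start),
                   end = as.integer(end), id = parts[, 1],
                   stringsAsFactors = FALSE)
  multi <- names(which(table(df$id) > 1))
  if (length(multi)) {
    warning(sprintf("gene(s) spanning multiple contigs: %s; using per-contig regions",
                    paste(multi, collapse = ", ")), call. = FALSE)
    sel <- df$id %in% multi
    df$id[sel] <- paste0(df$id[sel], "@", df$contig[sel])
  }
  df <- df[order(df$contig, df$start, df$end), , drop = FALSE]
  region_set(df)
}

#' Read a refGene-like transcript table
#'
#' Expects a header line and (at least) columns `gene`, `contig`,
#' `txStart`, `txEnd`; UCSC refGene's `name2`/`chrom` naming is also
#' accepted.
#'
#' @param path tab-delimited file.
#' @return data.frame with columns gene, contig, strand, txStart, txEnd.
#' @export
read_transcripts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  nm <- names(df)
  map <- c(gene = "name2", contig = "chrom")
  for (std in names(map))
    if (!std %in% nm && map[[std]] %in% nm) df[[std]] <- df[[map[[std]]]]
  if (!"strand" %in% names(df)) df$strand <- "+"
  need <- c("gene", "contig", "txStart", "txEnd")
  if (!all(need %in% names(df)))
    stop("transcript table needs columns gene, contig, txStart, txEnd",
         call. = FALSE)
  df[, c("gene", "contig", "strand", "txStart", "txEnd")]
}

#' Quantify a coverage track over regions
#'
#' Sum mode adds normalized counts over `[start, end)`; summit mode takes
#' the maximum within each region; mean mode divides the sum by the region
#' width. Overlapping regions are quantified independently.
#'
#' @param track a `CoverageTrack` from [make_track()].
#' @param regions a [region_set()] on the track's contigs.
#' @param mode one of `"sum"`, `"summit"`, `"mean"`.
#' @return named numeric vector, one value per region id.
#' @export
quantify_regions <- function(track, regions, mode = c("sum", "summit", "mean")) {
  mode <- match.arg(mode)
  out <- numeric(nrow(regions))
  names(out) <- regions$id
  for (ctg in unique(regions$contig)) {
    if (!ctg %in% names(track$cov))
      stop(sprintf("region contig '%s' absent from track", ctg), call. = FALSE)
    sel <- which(regions$contig == ctg)
    r <- track$cov[[ctg]]
    if (any(regions$end[sel] > length(r)))
      stop("region extends past contig end", call. = FALSE)
    v <- IRanges::Views(r, start = regions$start[sel] + 1L,
                        end = regions$end[sel])
    out[sel] <- switch(mode,
      sum = IRanges::viewSums(v),
      summit = IRanges::viewMaxs(v),
      mean = IRanges::viewSums(v) / (regions$end[sel] - regions$start[sel]))
  }
  out
}

#' Build a regions-by-samples quantification matrix
#'
#' @param tracks named list of `CoverageTrack`s (one per sample).
#' @param regions a [region_set()].
#' @param mode quantification mode, see [quantify_regions()].
#' @return A `QuantMatrix`: numeric matrix (regions x samples) with
#'   attributes `mode` and `regions`.
#' @export
build_quant_matrix <- function(tracks, regions, mode = c("sum", "summit", "mean")) {
  mode <- match.arg(mode)
  m <- vapply(tracks, quantify_regions, numeric(nrow(regions)),
              regions = regions, mode = mode)
  m <- matrix(m, nrow = nrow(regions),
              dimnames = list(regions$id, names(tracks)))
  structure(m, mode = mode, regions = regions, class = c("QuantMatrix", "matrix"))
}

#' Count fragments overlapping any region by at least one base pair
#'
#' Each fragment is counted once even when it overlaps several regions;
#' half-open semantics, so a fragment abutting a region does not count.
#'
#' @param fragments a [fragment_set()].
#' @param regions a [region_set()].
#' @return integer count (<= number of fragments).
#' @export
count_overlapping_fragments <- function(fragments, regions) {
  if (nrow(fragments) == 0 || nrow(regions) == 0) return(0L)
  hits <- GenomicRanges::findOverlaps(fragments_granges(fragments),
                                      regions_granges(regions),
                                      minoverlap = 1L)
  length(unique(S4Vectors::queryHits(hits)))
}

#' Cumulative log-log rank curve of per-region signal
#'
#' Regions are sorted by decreasing normalized count (zero-valued regions
#' dropped), cumulative sums taken, and `(log10 rank, log10 cumulative)`
#' pairs emitted. A higher curve indicates better concentration of signal
#' in annotated elements.
#'
#' @param values named per-region normalized counts.
#' @return data.frame with columns `rank`, `log10_rank`, `cumulative`,
#'   `log10_cumulative` (cumulative values non-decreasing).
#' @export
rank_curve <- function(values) {
  v <- values[values > 0]
  if (length(v) == 0) stop("all region values are zero", call. = FALSE)
  v <- sort(v, decreasing = TRUE)
  cs <- cumsum(v)
  data.frame(rank = seq_along(v), log10_rank = log10(seq_along(v)),
             cumulative = cs, log10_cumulative = log10(cs))
}

#' Squared correlation of log-transformed paired signals
#'
#' R^2 of the least-squares fit of `log10(y + pseudocount)` on
#' `log10(x + pseudocount)`; with a single predictor this equals the
#' squared Pearson correlation of the logged values. Inputs are matched
#' by name when both are named.
#'
#' @param x,y non-negative per-region or per-gene values.
#' @param pseudocount positive offset before logging (default 1).
#' @return R^2 in `[0, 1]`.
#' @export
scatter_r2 <- function(x, y, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
  if (!is.null(names(x)) && !is.null(names(y))) {
    shared <- intersect(names(x), names(y))
    x <- x[shared]; y <- y[shared]
  }
  if (length(x) != length(y)) stop("x and y must be matched", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 shared ids", call. = FALSE)
  stats::cor(log10(x + pseudocount), log10(y + pseudocount))^2
}

#' Summary statistics of a region annotation
#'
#' Record count, mean element length, and the fraction of the genome
#' covered by the union of the elements (computed on merged intervals).
#'
#' @param regions a [region_set()].
#' @param chrom_sizes data.frame (`contig`, `size`).
#' @return list with `n_regions`, `mean_length` (bp) and
#'   `genome_fraction` (proportion of total genome covered).
#' @export
annotation_stats <- function(regions, chrom_sizes) {
  gr <- GenomicRanges::reduce(regions_granges(regions))
  covered <- sum(as.numeric(GenomicRanges::width(gr)))
  list(n_regions = nrow(regions),
       mean_length = mean(regions$end - regions$start),
       genome_fraction = covered / sum(as.numeric(chrom_sizes$size)))
}

#' Write a QuantMatrix as TSV
#' @param qm a `QuantMatrix` from [build_quant_matrix()].
#' @param path output path.
#' @export
write_quant_matrix <- function(qm, path) {
  regions <- attr(qm, "regions")
  df <- data.frame(region_id = rownames(qm),
                   contig = regions$contig, start = regions$start,
                   end = regions$end, unclass(qm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
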