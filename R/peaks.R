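#' Parameters of the simplified Poisson peak caller
#'
#' The p-value threshold and keep-duplicates behaviour follow the
#' peak-calling command used for CUTAC data (`-p 1e-5 --keep-dup all`);
#' window size, local-background half-widths, merge gap and minimum peak
#' length are this caller's own documented defaults.
#'
#' @param p_threshold Poisson tail p-value threshold (default 1e-5).
#' @param window sliding-window width in bp (default 300).
#' @param step window step in bp (default 100).
#' @param local_halfwidths half-widths (bp) of the local-background
#'   windows (default 1,000 and 10,000).
#' @param merge_gap significant windows closer than this are merged (bp).
#' @param min_length peaks shorter than this are dropped (bp).
#' @return list of class `PeakCallParams`.
#' @export
peak_params <- function(p_threshold = 1e-5, window = 300L, step = 100L,
                        local_halfwidths = c(1000L, 10000L),
                        merge_gap = 100L, min_length = 150L) {
  if (p_threshold <= 0 || p_threshold >= 1)
    stop_field("p_threshold", "must lie in (0, 1)")
  if (window <= 0) stop_field("window", "must be positive")
  if (step <= 0 || step > window) stop_field("step", "must be in (0, window]")
  structure(list(p_threshold = p_threshold, window = as.integer(window),
                 step = as.integer(step),
                 local_halfwidths = as.integer(local_halfwidths),
                 merge_gap = as.integer(merge_gap),
                 min_length = as.integer(min_length)),
            class = "PeakCallParams")
}

count_in_windows <- function(mids_sorted, starts, width) {
  findInterval(starts + width, mids_sorted) -
    findInterval(starts, mids_sorted)
}

#' Call peaks with a sliding-window Poisson test
#'
#' Fragment midpoints are counted in sliding windows and tested against a
#' Poisson null whose rate is the maximum of the genome-wide expectation
#' and local-background expectations estimated in centered windows of
#' +/- 1 kb and +/- 10 kb. Significant windows (p below threshold) within
#' the merge gap are merged; merged peaks shorter than the minimum length
#' are dropped. Duplicate fragments are retained; the effective genome
#' size is the sum of the chrom.sizes. The caller is deterministic.
#' Remove mitochondrial fragments first ([remove_reference()]).
#'
#' @param fragments a non-empty [fragment_set()].
#' @param chrom_sizes data.frame (`contig`, `size`).
#' @param params a [peak_params()].
#' @return a [region_set()] of disjoint, sorted peaks with ids
#'   `peak_1 ...`, carrying a `p_value` attribute column-free summary.
#' @export
call_peaks <- function(fragments, chrom_sizes, params = peak_params()) {
  N <- nrow(fragments)
  if (N == 0) stop("cannot call peaks on an empty fragment set", call. = FALSE)
  G <- sum(as.numeric(chrom_sizes$size))
  win <- params$window
  lambda_bg_per_bp <- N / G
  out <- list()
  for (i in seq_len(nrow(chrom_sizes))) {
    ctg <- chrom_sizes$contig[i]
    L <- chrom_sizes$size[i]
    if (L < win) next
    sel <- fragments$contig == ctg
    if (!any(sel)) next
    mids <- sort((fragments$start[sel] + fragments$end[sel]) / 2)
    starts <- seq(0L, L - win, by = params$step)
    cnt <- count_in_windows(mids, starts, win)
    lambda <- rep(lambda_bg_per_bp * win, length(starts))
    centers <- starts + win / 2
    for (hw in params$local_halfwidths) {
      ls <- pmax(0, centers - hw)
      le <- pmin(L, centers + hw)
      loc <- (findInterval(le, mids) - findInterval(ls, mids)) / (le - ls) * win
      lambda <- pmax(lambda, loc)
    }
    p <- stats::ppois(cnt - 1, lambda, lower.tail = FALSE)
    sig <- which(p < params$p_threshold)
    if (!length(sig)) next
    ir <- IRanges::reduce(IRanges::IRanges(starts[sig] + 1L, starts[sig] + win),
                          min.gapwidth = params$merge_gap + 1L)
    keep <- IRanges::width(ir) >= params$min_length
    if (!any(keep)) next
    out[[ctg]] <- data.frame(contig = ctg,
                             start = IRanges::start(ir)[keep] - 1L,
                             end = IRanges::end(ir)[keep],
                             stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(region_set(data.frame(contig = character(0), start = integer(0),
                                 end = integer(0), id = character(0))))
  df <- do.call(rbind, out)
  df <- df[order(df$contig, df$start), , drop = FALSE]
  df$id <- sprintf("peak_%d", seq_len(nrow(df)))
  region_set(df)
}

#' Fraction of reads in peaks (FRiP)
#'
#' Fraction of fragments with at least one base pair of overlap with any
#' peak. An empty peak set gives 0.
#'
#' @param fragments a non-empty [fragment_set()].
#' @param peaks a [region_set()] of peaks.
#' @return fraction in `[0, 1]`.
#' @export
frip <- function(fragments, peaks) {
  if (nrow(fragments) == 0) stop("empty fragment set", call. = FALSE)
  if (nrow(peaks) == 0) return(0)
  count_overlapping_fragments(fragments, peaks) / nrow(fragments)
}

#' Downsampling sensitivity/specificity benchmark
#'
#' For each requested depth: draw a seeded subsample, remove mitochondrial
#' fragments, call peaks and compute FRiP. Peaks called measure
#' sensitivity; FRiP measures specificity. Depths larger than the input
#' are skipped with a warning.
#'
#' @param fragments a [fragment_set()] (all references; mito removed per
#'   depth after subsampling).
#' @param chrom_sizes chrom.sizes of the reference used for calling
#'   (nuclear contigs).
#' @param depths increasing vector of subsample sizes.
#' @param seed integer seed (one deterministic draw per depth).
#' @param params a [peak_params()].
#' @param mito_label reference label removed before calling.
#' @return A `BenchmarkCurve` data.frame: `depth`, `n_peaks`, `frip`.
#' @export
downsampling_benchmark <- function(fragments, chrom_sizes, depths, seed,
                                   params = peak_params(),
                                   mito_label = "mito") {
  depths <- sort(unique(as.integer(depths)))
  usable <- depths[depths <= nrow(fragments)]
  if (length(usable) < length(depths))
    warning(sprintf("skipping depth(s) beyond N = %d", nrow(fragments)),
            call. = FALSE)
  if (!length(usable)) stop("no usable depth", call. = FALSE)
  rows <- lapply(seq_along(usable), function(i) {
    sub <- subsample_fragments(fragments, usable[i], seed + i - 1L)
    sub <- remove_reference(sub, mito_label)
    pk <- call_peaks(sub, chrom_sizes, params)
    data.frame(depth = usable[i], n_peaks = nrow(pk),
               frip = frip(sub, pk))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("BenchmarkCurve", "data.frame")
  out
}

#' Read an externally produced narrowPeak file as a RegionSet
#'
#' Adapter point for substituting an external caller's output (e.g.
#' MACS2 narrowPeak) for the built-in caller.
#'
#' @param path narrowPeak (BED6+4) or any BED3+ file.
#' @return a [region_set()].
#' @export
read_narrowpeak <- function(path) read_regions(path)

#' Write peaks as a narrowPeak-like TSV
#' @param peaks a [region_set()].
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) write_regions(peaks, path)
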