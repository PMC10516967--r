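#' Genome-size-normalized per-base coverage track
#'
#' Depth counts full fragment extents; the value at base `b` is the number
#' of fragments overlapping `b` times `G / N`, where `G` is the total
#' reference size (sum of chrom.sizes) and `N` the number of fragments.
#' Under this scaling, uniformly distributed unit-length counts give value
#' 1 at each position, and the genome-wide mean of a track equals the mean
#' fragment length.
#'
#' @param fragments a [fragment_set()]; must be non-empty. All fragments
#'   are expected to lie on contigs of `chrom_sizes` (typically one
#'   reference, e.g. nuclear only).
#' @param chrom_sizes data.frame (`contig`, `size`) for the reference the
#'   track is computed over.
#' @return A `CoverageTrack`: list with `cov` (an [IRanges::RleList] of
#'   per-base normalized values, one element per contig), `scale` = G/N,
#'   `G`, `N` and `sample_id`.
#' @export
make_track <- function(fragments, chrom_sizes) {
  N <- nrow(fragments)
  if (N == 0) stop("cannot normalize an empty fragment set (N = 0)", call. = FALSE)
  validate_against_sizes(as.data.frame(fragments), chrom_sizes)
  G <- sum(as.numeric(chrom_sizes$size))
  scale <- G / N
  covs <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    ctg <- chrom_sizes$contig[i]
    sel <- fragments$contig == ctg
    ir <- IRanges::IRanges(fragments$start[sel] + 1L, fragments$end[sel])
    IRanges::coverage(ir, width = chrom_sizes$size[i]) * scale
  })
  names(covs) <- chrom_sizes$contig
  structure(list(cov = methods::as(covs, "SimpleRleList"),
                 scale = scale, G = G, N = N,
                 sample_id = attr(fragments, "sample_id")),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", length(x$cov), "contig(s),",
      x$N, "fragments, scale G/N =", format(x$scale), "\n")
  invisible(x)
}

#' Total mass of a coverage track
#'
#' Equals (total fragment bases) x G/N = mean fragment length x G.
#'
#' @param track a `CoverageTrack`.
#' @return numeric scalar.
#' @export
track_total <- function(track) {
  sum(vapply(track$cov, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                          S4Vectors::runLength(r)), 0))
}

#' Write a coverage track as run-length-encoded bedGraph
#'
#' Adjacent equal values are merged; zero runs are omitted, so an all-zero
#' track yields an empty data section. Values are written with 6 decimals.
#'
#' @param track a `CoverageTrack`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(track$cov)) {
    r <- track$cov[[ctg]]
    len <- S4Vectors::runLength(r)
    val <- S4Vectors::runValue(r)
    ends <- cumsum(as.numeric(len))
    starts <- ends - len
    keep <- val != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ctg,
                       as.integer(starts[keep]), as.integer(ends[keep]),
                       formatC(val[keep], format = "f", digits = 6)), con)
  }
  invisible(path)
}

#' Read a bedGraph file back into a CoverageTrack
#'
#' Bases not covered by any interval get value 0. The original scale
#' factor is not recoverable from the file and is stored as `NA`.
#'
#' @param path bedGraph file (0-based half-open).
#' @param chrom_sizes data.frame (`contig`, `size`).
#' @return a `CoverageTrack`.
#' @export
read_bedgraph <- function(path, chrom_sizes) {
  covs <- lapply(chrom_sizes$size, function(L) S4Vectors::Rle(0, L))
  names(covs) <- chrom_sizes$contig
  if (file.size(path) > 0) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("contig", "start", "end", "value"),
                            stringsAsFactors = FALSE)
    for (ctg in unique(df$contig)) {
      if (!ctg %in% names(covs)) stop(sprintf("unknown contig '%s'", ctg), call. = FALSE)
      sel <- df$contig == ctg
      v <- rep(0, chrom_sizes$size[match(ctg, chrom_sizes$contig)])
      for (i in which(sel)) v[(df$start[i] + 1L):df$end[i]] <- df$value[i]
      covs[[ctg]] <- S4Vectors::Rle(v)
    }
  }
  structure(list(cov = methods::as(covs, "SimpleRleList"),
                 scale = NA_real_, G = sum(as.numeric(chrom_sizes$size)),
                 N = NA_integer_, sample_id = basename(path)),
            class = "CoverageTrack")
}
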