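#' Construct a FragmentSet
#'
#' A FragmentSet holds one sample's mapped fragments in BED convention
#' (0-based half-open `[start, end)`), one row per sequenced fragment, with
#' a per-record reference label (e.g. `"nuclear"`, `"mito"`, `"contaminant"`)
#' and sample metadata.
#'
#' @param fragments data.frame with columns `contig`, `start`, `end` and
#'   optionally `reference` (defaults to `"nuclear"`).
#' @param sample_id sample identifier.
#' @param metadata named list of sample metadata (antibody, genotype,
#'   temperature, ...).
#' @param chrom_sizes optional data.frame (`contig`, `size`) to validate
#'   coordinates against.
#' @return data.frame of class `FragmentSet`.
#' @export
fragment_set <- function(fragments, sample_id = "sample",
                         metadata = list(), chrom_sizes = NULL) {
  need <- c("contig", "start", "end")
  if (!all(need %in% names(fragments)))
    stop("fragments need columns contig, start, end", call. = FALSE)
  df <- data.frame(
    contig = as.character(fragments$contig),
    start = as.integer(fragments$start),
    end = as.integer(fragments$end),
    stringsAsFactors = FALSE
  )
  df$reference <- if ("reference" %in% names(fragments))
    as.character(fragments$reference) else rep("nuclear", nrow(df))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop(sprintf("invalid fragment coordinates (start >= end or start < 0) at record(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  if (!is.null(chrom_sizes)) validate_against_sizes(df, chrom_sizes)
  structure(df, sample_id = sample_id, metadata = metadata,
            class = c("FragmentSet", "data.frame"))
}

validate_against_sizes <- function(df, chrom_sizes, lines = NULL) {
  sz <- stats::setNames(chrom_sizes$size, chrom_sizes$contig)
  unknown <- which(!(df$contig %in% names(sz)))
  if (length(unknown)) {
    where <- if (is.null(lines)) unknown else lines[unknown]
    stop(sprintf("unknown contig '%s' at line %d", df$contig[unknown[1]],
                 where[1]), call. = FALSE)
  }
  over <- which(df$end > sz[df$contig])
  if (length(over)) {
    where <- if (is.null(lines)) over else lines[over]
    stop(sprintf("fragment end exceeds contig length at line %d", where[1]),
         call. = FALSE)
  }
  invisible(df)
}

#' Number of fragments in a FragmentSet
#' @param fragments a [fragment_set()].
#' @return integer count.
#' @export
n_fragments <- function(fragments) nrow(fragments)

#' Fragment lengths (bp)
#' @param fragments a [fragment_set()].
#' @return integer vector `end - start`.
#' @export
fragment_lengths <- function(fragments) fragments$end - fragments$start

#' Read a chrom.sizes table
#'
#' @param path two-column tab-delimited file: contig name, length in bp.
#' @return data.frame with columns `contig`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "size"),
                          colClasses = c("character", "integer"))
  if (anyDuplicated(df$contig)) stop("duplicate contigs in chrom.sizes", call. = FALSE)
  df
}

#' Write a chrom.sizes table
#' @param chrom_sizes data.frame (`contig`, `size`).
#' @param path output path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(chrom_sizes[, c("contig", "size")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a mapped-fragment BED3+ file into a FragmentSet
#'
#' Every record is validated against the chrom.sizes table; malformed lines
#' are reported with their line number. An optional 4th column is taken as
#' the per-record reference label.
#'
#' @param path tab-delimited BED3+ file.
#' @param chrom_sizes data.frame (`contig`, `size`).
#' @param sample_id,metadata attached to the returned set.
#' @return a [fragment_set()].
#' @export
read_fragments <- function(path, chrom_sizes, sample_id = basename(path),
                           metadata = list()) {
  if (!file.exists(path) || file.size(path) == 0 ||
      length(readLines(path, n = 1)) == 0)
    stop(sprintf("empty fragment file: %s", path), call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           blank.lines.skip = FALSE)
  if (ncol(raw) < 3) stop("BED3+ requires at least 3 columns", call. = FALSE)
  df <- data.frame(contig = as.character(raw[[1]]),
                   start = suppressWarnings(as.integer(raw[[2]])),
                   end = suppressWarnings(as.integer(raw[[3]])),
                   stringsAsFactors = FALSE)
  if (ncol(raw) >= 4) df$reference <- as.character(raw[[4]])
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 | df$start >= df$end)
  if (length(bad))
    stop(sprintf("malformed fragment record at line %d (start must satisfy 0 <= start < end)",
                 bad[1]), call. = FALSE)
  validate_against_sizes(df, chrom_sizes, lines = seq_len(nrow(df)))
  fragment_set(df, sample_id = sample_id, metadata = metadata)
}

#' Write a FragmentSet as BED3+
#'
#' Tab-delimited, 0-based half-open; the 4th column carries the reference
#' label so that a round trip through [read_fragments()] is lossless.
#'
#' @param fragments a [fragment_set()].
#' @param path output path.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(
    as.data.frame(fragments)[, c("contig", "start", "end", "reference")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Seeded uniform subsampling of fragments without replacement
#'
#' Records are canonicalized (sorted by contig, start, end, reference)
#' before drawing, so the subsample does not depend on file line order.
#' Duplicate fragments are retained throughout the pipeline (peak calling
#' keeps duplicates), so the draw is over records, not unique positions.
#'
#' @param fragments a [fragment_set()].
#' @param n number of fragments to draw; must satisfy `0 < n <= N`.
#' @param seed integer seed making the draw deterministic.
#' @return a [fragment_set()] with `n` records and the same metadata.
#' @export
subsample_fragments <- function(fragments, n, seed) {
  N <- nrow(fragments)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (n > N) stop(sprintf("cannot draw %d fragments from a set of %d", n, N),
                  call. = FALSE)
  ord <- order(fragments$contig, fragments$start, fragments$end,
               fragments$reference, method = "radix")
  canon <- as.data.frame(fragments)[ord, , drop = FALSE]
  keep <- with_seed(seed, sample.int(N, n))
  fragment_set(canon[keep, , drop = FALSE],
               sample_id = attr(fragments, "sample_id"),
               metadata = attr(fragments, "metadata"))
}

#' Drop all fragments with a given reference label
#'
#' Used to remove mitochondrial fragments before peak calling. Removing a
#' label that is not present is a no-op.
#'
#' @param fragments a [fragment_set()].
#' @param label reference label to remove (e.g. `"mito"`).
#' @return a [fragment_set()].
#' @export
remove_reference <- function(fragments, label) {
  keep <- fragments$reference != label
  fragment_set(as.data.frame(fragments)[keep, , drop = FALSE],
               sample_id = attr(fragments, "sample_id"),
               metadata = attr(fragments, "metadata"))
}

#' Construct a RegionSet
#'
#' Named half-open intervals: cCREs, winnowed genes or called peaks.
#'
#' @param regions data.frame with columns `contig`, `start`, `end` and
#'   optionally `id` (generated as `region_<k>` when absent).
#' @return data.frame of class `RegionSet`.
#' @export
region_set <- function(regions) {
  need <- c("contig", "start", "end")
  if (!all(need %in% names(regions)))
    stop("regions need columns contig, start, end", call. = FALSE)
  df <- data.frame(contig = as.character(regions$contig),
                   start = as.integer(regions$start),
                   end = as.integer(regions$end),
                   stringsAsFactors = FALSE)
  df$id <- if ("id" %in% names(regions)) as.character(regions$id)
           else sprintf("region_%d", seq_len(nrow(df)))
  if (any(df$start >= df$end))
    stop("region start must be < end", call. = FALSE)
  if (anyDuplicated(df$id)) stop("region ids must be unique", call. = FALSE)
  structure(df, class = c("RegionSet", "data.frame"))
}

#' Read a BED file of regions
#' @param path BED3/BED4 file (4th column used as id when present).
#' @return a [region_set()].
#' @export
read_regions <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  df <- data.frame(contig = as.character(raw[[1]]),
                   start = as.integer(raw[[2]]),
                   end = as.integer(raw[[3]]),
                   stringsAsFactors = FALSE)
  if (ncol(raw) >= 4) df$id <- as.character(raw[[4]])
  region_set(df)
}

#' Write a RegionSet as BED4
#' @param regions a [region_set()].
#' @param path output path.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(as.data.frame(regions)[, c("contig", "start", "end", "id")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

fragments_granges <- function(fragments) {
  GenomicRanges::GRanges(fragments$contig,
                         IRanges::IRanges(fragments$start + 1L, fragments$end))
}

regions_granges <- function(regions) {
  GenomicRanges::GRanges(regions$contig,
                         IRanges::IRanges(regions$start + 1L, regions$end))
}
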