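# Shared fixtures and independent brute-force oracles.

small_config <- function(seed = 101, ...) {
  args <- utils::modifyList(list(
    seed = seed,
    genome_spec = data.frame(
      contig = c("chr1", "chrM", "contam1"),
      length = c(1e6, 16299, 5e5),
      role = c("nuclear", "mito", "contaminant")),
    n_ccres = 150L,
    n_samples_per_group = 2L,
    fragments_per_sample = 20000L,
    n_genes = 30L), list(...))
  do.call(sim_config, args)
}

random_fragments <- function(n, G, contig = "chr1", max_len = 80) {
  start <- sample.int(G - max_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  fragment_set(data.frame(contig = contig, start = start, end = start + len))
}

# per-base accumulation oracle for normalized coverage
brute_track_values <- function(fragments, G) {
  v <- numeric(G)
  for (i in seq_len(nrow(fragments))) {
    idx <- (fragments$start[i] + 1L):fragments$end[i]
    v[idx] <- v[idx] + 1
  }
  v * G / nrow(fragments)
}

# all-pairs >=1 bp overlap oracle (half-open intervals)
brute_overlap_count <- function(fragments, regions) {
  hit <- logical(nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    for (j in seq_len(nrow(regions))) {
      if (fragments$contig[i] == regions$contig[j] &&
          fragments$start[i] < regions$end[j] &&
          fragments$end[i] > regions$start[j]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  sum(hit)
}

nuclear_only <- function(fs) remove_reference(remove_reference(fs, "mito"),
                                              "contaminant")
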