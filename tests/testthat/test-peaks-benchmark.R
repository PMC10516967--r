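make_enriched <- function(n_total = 5000, n_in = 500, G = 1e6,
                          site = c(500000L, 500400L), seed = 21) {
  set.seed(seed)
  bg <- n_total - n_in
  start_bg <- sample.int(G - 100L, bg, replace = TRUE) - 1L
  start_in <- site[1] + sample.int(diff(site) - 60L, n_in, replace = TRUE) - 1L
  len <- sample(40:80, n_total, replace = TRUE)
  fragment_set(data.frame(contig = "chr1",
                          start = c(start_bg, start_in),
                          end = c(start_bg, start_in) + len))
}

cs1 <- data.frame(contig = "chr1", size = 1e6)

test_that("uniform background yields essentially no peaks", {
  set.seed(55)
  fs <- random_fragments(50000, 1e6)
  pk <- call_peaks(fs, cs1)
  expect_lte(nrow(pk), 2)
})

test_that("a strong constructed site is called as exactly one covering peak", {
  fs <- make_enriched()
  pk <- call_peaks(fs, cs1)
  expect_equal(nrow(pk), 1L)
  expect_lte(pk$start[1], 500000)
  expect_gte(pk$end[1], 500400)
})

test_that("peaks are disjoint, sorted, and enriched above the null expectation", {
  cfg <- small_config(seed = 43, fragments_per_sample = 40000L,
                      n_samples_per_group = 1L)
  exp <- generate_experiment(cfg)
  fs <- nuclear_only(exp$fragments[[1]])
  nuc_cs <- data.frame(contig = "chr1", size = 1e6)
  pk <- call_peaks(fs, nuc_cs)
  expect_gt(nrow(pk), 5)
  expect_true(all(pk$start[-1] >= pk$end[-nrow(pk)]))
  expect_true(all(pk$end - pk$start >= peak_params()$min_length))
  # every peak holds more fragments than the genome-wide expectation
  lambda_bp <- nrow(fs) / 1e6
  mids <- (fs$start + fs$end) / 2
  for (i in seq_len(nrow(pk))) {
    cnt <- sum(mids >= pk$start[i] & mids < pk$end[i])
    expect_gt(cnt, lambda_bp * (pk$end[i] - pk$start[i]))
  }
})

test_that("doubling every fragment keeps or grows the called peaks", {
  fs <- make_enriched(n_total = 3000, n_in = 200)
  dbl <- fragment_set(rbind(as.data.frame(fs), as.data.frame(fs)))
  pk1 <- call_peaks(fs, cs1)
  pk2 <- call_peaks(dbl, cs1)
  expect_gte(nrow(pk2), nrow(pk1))
  # original peaks remain covered
  if (nrow(pk1) > 0) {
    for (i in seq_len(nrow(pk1))) {
      covered <- any(pk2$start <= pk1$start[i] & pk2$end >= pk1$end[i])
      expect_true(covered)
    }
  }
})

test_that("FRiP counts >=1 bp overlaps per fragment, matching the oracle", {
  peaks <- region_set(data.frame(contig = "chr1",
                                 start = c(100L, 1000L), end = c(200L, 1200L)))
  fs <- fragment_set(data.frame(
    contig = "chr1",
    start = c(150L, 199L, 200L, 995L, 1199L, 5000L, 40L, 1100L, 90L, 210L),
    end   = c(160L, 210L, 230L, 1005L, 1210L, 5050L, 99L, 1150L, 101L, 240L)))
  # overlapping: 150,199,995,1199,1100,90(end 101 > 100) -> 6; plus 200 abuts (no)
  expect_equal(frip(fs, peaks), 0.6)
  expect_equal(brute_overlap_count(fs, peaks), 6L)
  expect_equal(frip(fs, region_set(data.frame(contig = "chr1", start = 0L,
                                              end = 10000L))), 1)
  empty <- region_set(data.frame(contig = character(0), start = integer(0),
                                 end = integer(0), id = character(0)))
  expect_equal(frip(fs, empty), 0)
})

test_that("interval-index FRiP equals brute force on random instances", {
  set.seed(77)
  for (rep in 1:8) {
    G <- 10000L
    fs <- random_fragments(300, G)
    rg <- region_set(data.frame(contig = "chr1",
                                start = s <- sort(sample.int(G - 200L, 10)) - 1L,
                                end = s + sample(20:150, 10, replace = TRUE)))
    expect_equal(count_overlapping_fragments(fs, rg),
                 brute_overlap_count(fs, rg))
  }
})

test_that("benchmark at full depth reproduces a single-shot call, and FRiP beats random regions", {
  fs <- make_enriched(n_total = 4000, n_in = 400)
  bench <- downsampling_benchmark(fs, cs1, depths = c(2000, 4000), seed = 9)
  expect_s3_class(bench, "data.frame")
  expect_equal(bench$depth, c(2000L, 4000L))
  full <- subsample_fragments(fs, 4000, seed = 9 + 1L)
  pk <- call_peaks(full, cs1)
  expect_equal(bench$n_peaks[2], nrow(pk))
  expect_equal(bench$frip[2], frip(full, pk))

  # specificity sanity: own peaks beat a shifted decoy of equal total length
  decoy <- region_set(data.frame(contig = "chr1",
                                 start = pk$start + 200000L,
                                 end = pk$end + 200000L))
  expect_gte(frip(fs, pk), frip(fs, decoy))

  expect_warning(downsampling_benchmark(fs, cs1, depths = c(2000, 1e7),
                                        seed = 1), "skipping")
  expect_error(suppressWarnings(
    downsampling_benchmark(fs, cs1, depths = 1e7, seed = 1)),
    "no usable depth")
})

test_that("external narrowPeak files are accepted as peak sets", {
  p <- tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t400\tpk1\t0\t.\t5.1\t8.2\t6.0\t150",
               "chr1\t900\t1300\tpk2\t0\t.\t4.0\t6.0\t5.0\t200"), p)
  pk <- read_narrowpeak(p)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$id, c("pk1", "pk2"))
  unlink(p)
})
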