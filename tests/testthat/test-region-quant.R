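test_that("gene winnowing spans min start to max end per gene", {
  tx <- data.frame(gene = c("A", "A", "B"), contig = "chr1",
                   txStart = c(100L, 300L, 2000L), txEnd = c(500L, 900L, 2500L))
  g <- winnow_genes(tx)
  expect_equal(g$start[g$id == "A"], 100L)
  expect_equal(g$end[g$id == "A"], 900L)
  expect_equal(g$start[g$id == "B"], 2000L)

  # shuffled rows give identical output
  g2 <- winnow_genes(tx[c(3, 1, 2), ])
  expect_equal(as.data.frame(g), as.data.frame(g2))

  # multi-contig gene splits with suffixed ids and a warning
  tx2 <- rbind(tx, data.frame(gene = "A", contig = "chr2",
                              txStart = 10L, txEnd = 50L))
  expect_warning(g3 <- winnow_genes(tx2), "multiple contigs")
  expect_setequal(g3$id[grepl("^A", g3$id)], c("A@chr1", "A@chr2"))
})

test_that("sum and summit quantification match hand values and the oracle", {
  cov <- methods::as(list(c = S4Vectors::Rle(c(0, 0, 2, 3, 0))), "SimpleRleList")
  tr <- structure(list(cov = cov, scale = 1, G = 5, N = 1, sample_id = "x"),
                  class = "CoverageTrack")
  rg <- region_set(data.frame(contig = "c", start = 1L, end = 4L))
  expect_equal(unname(quantify_regions(tr, rg, "sum")), 5)
  expect_equal(unname(quantify_regions(tr, rg, "summit")), 3)
  expect_equal(unname(quantify_regions(tr, rg, "mean")), 5 / 3)

  zero <- structure(list(cov = methods::as(list(c = S4Vectors::Rle(0, 5L)),
                                           "SimpleRleList"),
                         scale = 1, G = 5, N = 1, sample_id = "z"),
                    class = "CoverageTrack")
  expect_equal(unname(quantify_regions(zero, rg, "sum")), 0)
  expect_equal(unname(quantify_regions(zero, rg, "summit")), 0)

  expect_error(quantify_regions(tr, region_set(
    data.frame(contig = "c", start = 2L, end = 9L))), "past contig end")

  set.seed(5)
  G <- 5000L
  fs <- random_fragments(200, G)
  track <- make_track(fs, data.frame(contig = "chr1", size = G))
  v <- brute_track_values(fs, G)
  regions <- region_set(data.frame(
    contig = "chr1", start = s <- sort(sample.int(G - 300L, 15)) - 1L,
    end = s + sample(50:250, 15, replace = TRUE)))
  expect_equal(unname(quantify_regions(track, regions, "sum")),
               vapply(seq_len(15), function(i)
                 sum(v[(regions$start[i] + 1):regions$end[i]]), 0))
  expect_equal(unname(quantify_regions(track, regions, "summit")),
               vapply(seq_len(15), function(i)
                 max(v[(regions$start[i] + 1):regions$end[i]]), 0))
})

test_that("sum quantification over a genome partition conserves track mass", {
  set.seed(6)
  G <- 4000L
  fs <- random_fragments(150, G)
  tr <- make_track(fs, data.frame(contig = "chr1", size = G))
  cuts <- c(0L, sort(sample.int(G - 1L, 7)), G)
  part <- region_set(data.frame(contig = "chr1", start = cuts[-length(cuts)],
                                end = cuts[-1]))
  expect_equal(sum(quantify_regions(tr, part, "sum")), track_total(tr),
               tolerance = 1e-9)
})

test_that("overlap counting uses half-open semantics and counts fragments once", {
  rgA <- region_set(data.frame(contig = "c", start = 19L, end = 30L))
  rgB <- region_set(data.frame(contig = "c", start = 20L, end = 30L))
  fs <- fragment_set(data.frame(contig = "c", start = 10L, end = 20L))
  expect_equal(count_overlapping_fragments(fs, rgA), 1L)
  expect_equal(count_overlapping_fragments(fs, rgB), 0L)
  two <- region_set(data.frame(contig = "c", start = c(0L, 15L),
                               end = c(12L, 25L)))
  expect_equal(count_overlapping_fragments(fs, two), 1L)
})

test_that("rank curves are cumulative, monotone, and match closed forms", {
  v <- rep(2.5, 8)
  rc <- rank_curve(v)
  expect_equal(rc$log10_cumulative, log10(2.5 * seq_len(8)))
  expect_equal(diff(rc$cumulative) >= 0, rep(TRUE, 7))

  one <- rank_curve(c(x = 7))
  expect_equal(nrow(one), 1L)
  expect_equal(one$log10_rank, 0)
  expect_equal(one$log10_cumulative, log10(7))

  expect_error(rank_curve(c(0, 0)), "zero")

  # enriched sample curve dominates background-only at shared ranks
  cfg <- small_config(seed = 47, fragments_per_sample = 30000L,
                      n_samples_per_group = 1L)
  exp <- generate_experiment(cfg)
  nuc_cs <- data.frame(contig = "chr1", size = 1e6)
  fs <- nuclear_only(exp$fragments[[1]])
  tr <- make_track(fs, nuc_cs)
  q_enr <- quantify_regions(tr, exp$ccres, "sum")
  set.seed(1)
  bg <- random_fragments(n_fragments(fs), 1e6)
  q_bg <- quantify_regions(make_track(bg, nuc_cs), exp$ccres, "sum")
  rc_enr <- rank_curve(q_enr)
  rc_bg <- rank_curve(q_bg)
  shared <- seq_len(min(nrow(rc_enr), nrow(rc_bg)))
  expect_true(all(rc_enr$log10_cumulative[shared] >=
                    rc_bg$log10_cumulative[shared]))
})

test_that("scatter R^2 matches squared Pearson on logged values", {
  set.seed(9)
  x <- rlnorm(200, 3, 1)
  expect_equal(scatter_r2(x, x), 1.0)
  y <- rlnorm(200, 3, 1)
  expect_lt(scatter_r2(x, y), 0.1)
  expect_equal(scatter_r2(x, y),
               cor(log10(x + 1), log10(y + 1))^2)
  expect_error(scatter_r2(x[1:2], y[1:2]), "3")
  expect_error(scatter_r2(x, y, pseudocount = 0), "positive")
  # name matching
  names(x) <- paste0("g", seq_along(x))
  y2 <- x[sample(names(x))]
  expect_equal(scatter_r2(x, y2), 1.0)
})

test_that("annotation statistics match a brute-force union computation", {
  set.seed(12)
  cs <- data.frame(contig = "chr1", size = 100000L)
  st <- sort(sample.int(99000L, 50)) - 1L
  rg <- region_set(data.frame(contig = "chr1", start = st,
                              end = st + sample(100:500, 50, replace = TRUE)))
  stats <- annotation_stats(rg, cs)
  expect_equal(stats$n_regions, 50L)
  expect_equal(stats$mean_length, mean(rg$end - rg$start))
  covered <- logical(100000L)
  for (i in seq_len(50)) covered[(rg$start[i] + 1):rg$end[i]] <- TRUE
  expect_equal(stats$genome_fraction, sum(covered) / 100000)
})

test_that("replicate pairs correlate more strongly than cross-group pairs", {
  cfg <- small_config(seed = 53, fragments_per_sample = 30000L,
                      frac_up_regions = 0.1, effect_logfc = 2)
  exp <- generate_experiment(cfg)
  nuc_cs <- data.frame(contig = "chr1", size = 1e6)
  tracks <- lapply(exp$fragments, function(f) make_track(nuclear_only(f), nuc_cs))
  qm <- build_quant_matrix(tracks, exp$ccres, "sum")
  g <- exp$sample_sheet$genotype
  rep_pair <- scatter_r2(qm[, which(g == "Normal")[1]],
                         qm[, which(g == "Normal")[2]])
  cross_pair <- scatter_r2(qm[, which(g == "Normal")[1]],
                           qm[, which(g != "Normal")[1]])
  expect_gt(rep_pair, cross_pair)
})
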