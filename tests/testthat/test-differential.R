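test_that("log-cpm transform matches the closed formula", {
  m <- matrix(c(0, 10, 1e6 - 1, 90, 10, 900), nrow = 3,
              dimnames = list(paste0("r", 1:3), c("s1", "s2")))
  lc <- log_cpm(m)
  tot1 <- sum(m[, 1])
  expect_equal(lc$logged[1, 1], log2(0.5 / (tot1 + 1) * 1e6))
  expect_equal(lc$logged[3, 1], log2((1e6 - 1 + 0.5) / (tot1 + 1) * 1e6))
  expect_equal(lc$lib_size, c(s1 = tot1, s2 = 1000))
  expect_error(log_cpm(matrix(0, 2, 2)), "zero library")
  expect_error(log_cpm(matrix(-1, 2, 2)), "negative")

  # scale invariance for large totals
  big <- matrix(rpois(2000, 500) + 1, ncol = 4)
  d1 <- log_cpm(big)$logged
  d2 <- log_cpm(big * 10)$logged
  expect_lt(max(abs(d1 - d2)), 0.01)
})

test_that("voom weights are near-constant for homoscedastic data and track trends", {
  sim <- simulate_quant_matrix(2000, seed = 61)
  lc <- log_cpm(sim$matrix)
  w <- voom_weights(lc$logged, sim$groups)
  expect_true(all(w > 0))
  expect_lt(max(w) / min(w), 2)

  # constructed mean-variance trend: noisier at low signal -> lower weights
  set.seed(62)
  n <- 2000
  mu <- sort(rnorm(n, 8, 1.5))
  sds <- seq(0.8, 0.1, length.out = n)
  m <- 2^(mu + matrix(rnorm(n * 10, 0, sds), n, 10))
  lc2 <- log_cpm(m)
  w2 <- voom_weights(lc2$logged, rep(c("A", "B"), each = 5))
  expect_lt(mean(w2[1:200, ]), mean(w2[(n - 199):n, ]))

  # weights invariant to region ordering
  perm <- sample(n)
  w3 <- voom_weights(lc2$logged[perm, ], rep(c("A", "B"), each = 5))
  expect_equal(w3, w2[perm, ], tolerance = 1e-10)

  expect_error(voom_weights(lc$logged[, 1, drop = FALSE], "A"), "2 samples")
  expect_error(voom_weights(matrix(5, 10, 4), rep(c("A", "B"), 2)), "constant")
})

test_that("shrinkage formula and trigamma inversion are exact", {
  expect_equal(posterior_variance(4, 2, 4, 1), 2)
  expect_equal(posterior_variance(c(1, 9), 3, 0, 5), c(1, 9))
  expect_equal(posterior_variance(c(1, 9), 3, Inf, 5), c(5, 5))
  s2 <- c(0.5, 2, 4)
  ps <- posterior_variance(s2, 3, 2, 1.5)
  expect_true(all(ps >= pmin(s2, 1.5) & ps <= pmax(s2, 1.5)))
  for (y in c(0.01, 0.3, 2, 50)) {
    expect_equal(trigamma(trigamma_inverse(y)), y, tolerance = 1e-6)
  }
})

test_that("the variance prior is recovered from scaled-F samples", {
  set.seed(63)
  d0 <- 8; s0 <- 1.4; d <- 6
  s2 <- s0 * rf(20000, d, d0)
  prior <- estimate_variance_prior(s2, d)
  expect_equal(prior$d0, d0, tolerance = 0.15)
  expect_equal(prior$s0_2, s0, tolerance = 0.1)

  # estimated d0 grows as heterogeneity shrinks
  d0_het <- sapply(c(0.8, 0.1), function(h) {
    sim <- simulate_quant_matrix(3000, sigma_het = h, seed = 64)
    lc <- log_cpm(sim$matrix)
    attr(moderated_test(lc$logged, sim$groups, c("B", "A")), "d0")
  })
  expect_gt(d0_het[2], d0_het[1])
})

test_that("with d0 = 0 the moderated t equals the ordinary weighted t", {
  sim <- simulate_quant_matrix(500, seed = 65, sigma_het = 0.5)
  lc <- log_cpm(sim$matrix)
  res <- moderated_test(lc$logged, sim$groups, c("B", "A"), prior_df = 0)
  # ordinary two-sample pooled t per region
  g <- sim$groups
  for (i in c(1, 50, 400)) {
    tt <- t.test(lc$logged[i, g == "B"], lc$logged[i, g == "A"],
                 var.equal = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("swapping the contrast negates logFC and preserves p-values", {
  sim <- simulate_quant_matrix(800, frac_up = 0.05, effect_logfc = 1,
                               seed = 66, sigma_het = 0.3)
  lc <- log_cpm(sim$matrix)
  w <- voom_weights(lc$logged, sim$groups)
  ab <- moderated_test(lc$logged, sim$groups, c("B", "A"), weights = w)
  ba <- moderated_test(lc$logged, sim$groups, c("A", "B"), weights = w)
  expect_equal(ab$logfc, -ba$logfc)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("pseudo-replicate groups add residual df without entering the contrast", {
  sim <- simulate_quant_matrix(600, groups = c("A", "B", "C"),
                               n_per_group = 3, seed = 67)
  lc <- log_cpm(sim$matrix)
  res3 <- moderated_test(lc$logged, sim$groups, c("B", "A"))
  expect_equal(attr(res3, "df_resid"), 9 - 3)
  keep <- sim$groups %in% c("A", "B")
  res2 <- moderated_test(lc$logged[, keep], droplevels(sim$groups[keep]),
                         c("B", "A"))
  # same contrast estimate (unweighted group means), more pooled df with C
  expect_equal(res3$logfc, res2$logfc)
  expect_gt(attr(res3, "df_resid"), attr(res2, "df_resid"))
})

test_that("results agree with an independent reference implementation", {
  skip_if_not_installed("limma")
  sim <- simulate_quant_matrix(1500, frac_up = 0.05, effect_logfc = 1.2,
                               sigma_het = 0.5, seed = 68)
  counts <- round(sim$matrix)
  lc <- log_cpm(counts)
  w <- voom_weights(lc$logged, sim$groups)
  mine <- moderated_test(lc$logged, sim$groups, c("B", "A"), weights = w)
  design <- stats::model.matrix(~ 0 + sim$groups)
  colnames(design) <- levels(sim$groups)
  v <- limma::voom(counts, design)
  fit <- limma::lmFit(v, design)
  fit <- limma::contrasts.fit(fit, limma::makeContrasts(B - A, levels = design))
  fit <- limma::eBayes(fit)
  expect_gt(cor(mine$logfc, fit$coefficients[, 1]), 0.999)
  expect_gt(cor(mine$t, fit$t[, 1]), 0.99)
  expect_equal(attr(mine, "d0"), fit$df.prior, tolerance = 0.05)
  top_m <- mine$region_id[order(mine$p_value)][1:50]
  top_l <- rownames(counts)[order(fit$p.value[, 1])][1:50]
  expect_gte(length(intersect(top_m, top_l)), 45)
})

test_that("BH step-up matches hand evaluation and the standard implementation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(69)
  p <- runif(200)^1.5
  expect_equal(bh_fdr(p), p.adjust(p, "BH"))
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= 0))
})

test_that("list concordance handles worked ratios and edge cases", {
  a <- sprintf("g%d", 1:63)
  b <- c(sprintf("g%d", 1:52), sprintf("x%d", 1:40))
  lc <- list_concordance(a, b)
  expect_equal(lc$shared, 52L)
  expect_equal(lc$fraction, 52 / 63)
  expect_equal(list_concordance(a, a)$fraction, 1.0)
  expect_equal(list_concordance(a, paste0("z", a))$fraction, 0)
  empty <- list_concordance(character(0), a)
  expect_equal(empty$fraction, 0)
  expect_false(empty$defined)
})

test_that("null configurations keep FDR discoveries at the nominal level", {
  hits <- sapply(1:10, function(i) {
    sim <- simulate_quant_matrix(2000, seed = 700 + i)
    lc <- log_cpm(sim$matrix)
    res <- moderated_test(lc$logged, sim$groups, c("B", "A"),
                          weights = voom_weights(lc$logged, sim$groups))
    mean(res$fdr < 0.05)
  })
  expect_lte(mean(hits), 0.05)
})
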