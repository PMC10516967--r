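#' Log2 counts-per-million transform
#'
#' `value -> log2((value + 0.5) / (library_total + 1) * 1e6)`, the
#' standard transform preceding precision-weight estimation.
#'
#' @param mat non-negative regions x samples matrix (a `QuantMatrix` or
#'   plain matrix).
#' @return list with `logged` (matrix of log2-cpm values) and `lib_size`
#'   (per-sample totals).
#' @export
log_cpm <- function(mat) {
  m <- unclass(mat)
  if (any(m < 0)) stop("negative values in quantification matrix", call. = FALSE)
  lib <- colSums(m)
  if (any(lib == 0)) stop("zero library total for sample(s): ",
                          paste(colnames(m)[lib == 0], collapse = ", "),
                          call. = FALSE)
  logged <- log2(sweep(m + 0.5, 2, lib + 1, "/") * 1e6)
  list(logged = logged, lib_size = lib)
}

group_design <- function(groups) {
  g <- as.factor(groups)
  if (any(table(g) < 1)) stop("empty group", call. = FALSE)
  stats::model.matrix(~ 0 + g)
}

fit_group_means <- function(x, groups, weights = NULL) {
  g <- as.factor(groups)
  lev <- levels(g)
  n <- ncol(x)
  if (is.null(weights)) weights <- matrix(1, nrow(x), n)
  mu <- matrix(0, nrow(x), length(lev), dimnames = list(rownames(x), lev))
  sw <- matrix(0, nrow(x), length(lev), dimnames = list(rownames(x), lev))
  for (l in lev) {
    idx <- which(g == l)
    w <- weights[, idx, drop = FALSE]
    sw[, l] <- rowSums(w)
    mu[, l] <- rowSums(w * x[, idx, drop = FALSE]) / sw[, l]
  }
  fitted <- mu[, as.character(g), drop = FALSE]
  resid <- x - fitted
  df_resid <- n - length(lev)
  s2 <- rowSums(weights * resid^2) / df_resid
  list(mu = mu, sum_w = sw, fitted = fitted, s2 = s2, df_resid = df_resid)
}

#' Voom-style precision weights
#'
#' Fits per-region group means, smooths the square-root residual standard
#' deviation against average log2 signal with lowess (span 0.5), predicts
#' the sd at each observation's fitted value, and returns
#' `predicted_sd^-4` as the observation weight.
#'
#' @param logged log2-cpm matrix from [log_cpm()].
#' @param groups group label per sample (factor or character), including
#'   any pseudo-replicate groups.
#' @param span lowess span (default 0.5).
#' @return matrix of positive observation weights, same shape as `logged`.
#' @export
voom_weights <- function(logged, groups, span = 0.5) {
  if (ncol(logged) < 2) stop("need at least 2 samples", call. = FALSE)
  fit <- fit_group_means(logged, groups)
  if (fit$df_resid < 1) stop("no residual degrees of freedom", call. = FALSE)
  sd_res <- sqrt(fit$s2)
  if (all(sd_res == 0)) stop("all regions constant; cannot estimate a trend",
                             call. = FALSE)
  avg <- rowMeans(logged)
  lo <- stats::lowess(avg, sqrt(sd_res), f = span)
  pred <- stats::approx(lo$x, lo$y, xout = as.vector(fit$fitted),
                        rule = 2, ties = mean)$y
  pred <- pmax(pred, 1e-2)   # guard against non-positive trend predictions
  matrix(pred^-4, nrow = nrow(logged), ncol = ncol(logged),
         dimnames = dimnames(logged))
}

#' Invert the trigamma function
#'
#' Newton iteration solving `trigamma(x) = y`, used in moment-matching
#' estimation of the empirical-Bayes prior degrees of freedom.
#'
#' @param y positive target value.
#' @return x with `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Estimate the empirical-Bayes variance prior by moment matching
#'
#' Matches the mean and variance of `log(s^2)` to a scaled-F marginal:
#' with `e = log(s2) - digamma(d/2) + log(d/2)`,
#' `var(e) - trigamma(d/2) = trigamma(d0/2)` determines the prior degrees
#' of freedom `d0` (trigamma inversion) and
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))` the prior variance.
#' When the excess variance is non-positive the prior is degenerate
#' (`d0 = Inf`, `s0^2 = exp(mean(e))`).
#'
#' @param s2 per-region residual variances.
#' @param df residual degrees of freedom (scalar).
#' @return list with `d0` (prior df) and `s0_2` (prior variance).
#' @export
estimate_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  if (!any(ok)) stop("all residual variances are zero", call. = FALSE)
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_2 = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

#' Posterior (shrunken) variance
#'
#' `s2_post = (d0 * s0_2 + df * s2) / (d0 + df)`; with `d0 = 0` the raw
#' variance is returned, with `d0 = Inf` the prior variance.
#'
#' @param s2 per-region residual variances.
#' @param df residual degrees of freedom.
#' @param d0 prior degrees of freedom.
#' @param s0_2 prior variance.
#' @return vector of posterior variances, each between `min(s0_2, s2)`
#'   and `max(s0_2, s2)`.
#' @export
posterior_variance <- function(s2, df, d0, s0_2) {
  if (is.infinite(d0)) return(rep(s0_2, length(s2)))
  (d0 * s0_2 + df * s2) / (d0 + df)
}

#' Empirical-Bayes moderated two-group comparison
#'
#' Weighted least-squares group means are fit per region with one
#' coefficient per group; all non-contrast groups enter the fit as
#' pseudo-replicates, contributing residual degrees of freedom and
#' variance pooling but not the contrast estimate. Residual variances are
#' shrunk toward a moment-matched scaled-F prior
#' ([estimate_variance_prior()]), and the contrast `A - B` is tested with
#' a moderated t on `d0 + df` degrees of freedom. FDR is Benjamini-
#' Hochberg across all regions tested ([bh_fdr()]).
#'
#' @param logged log2 matrix from [log_cpm()].
#' @param groups group label per sample (all groups, including
#'   pseudo-replicates).
#' @param contrast length-2 character vector `c(A, B)`; the log-fold
#'   change reported is A minus B.
#' @param weights observation weights from [voom_weights()] (default
#'   unweighted).
#' @param prior_df override of the prior degrees of freedom: `NULL`
#'   (estimate), `0` (no shrinkage; ordinary weighted t) or `Inf`.
#' @return A `DiffResult` data.frame: `region_id`, `avg_log2`, `logfc`,
#'   `t`, `p_value`, `fdr`, `neg_log10_fdr`, `neg_log10_p`, `s2`,
#'   `s2_post`; attributes `d0`, `s0_2`, `df_resid`, `contrast`.
#' @export
moderated_test <- function(logged, groups, contrast, weights = NULL,
                           prior_df = NULL) {
  g <- as.factor(groups)
  if (length(contrast) != 2 || !all(contrast %in% levels(g)))
    stop("contrast must name two groups present in 'groups'", call. = FALSE)
  if (ncol(logged) != length(g))
    stop("groups length must match number of samples", call. = FALSE)
  fit <- fit_group_means(logged, g, weights)
  if (fit$df_resid < 1)
    stop("no residual degrees of freedom (need more samples than groups)",
         call. = FALSE)
  logfc <- fit$mu[, contrast[1]] - fit$mu[, contrast[2]]
  u2 <- 1 / fit$sum_w[, contrast[1]] + 1 / fit$sum_w[, contrast[2]]
  s2 <- fit$s2
  if (is.null(prior_df)) {
    if (stats::var(s2) == 0) {
      warning("residual variances are all equal; using a degenerate prior (d0 = Inf)",
              call. = FALSE)
      prior <- list(d0 = Inf, s0_2 = s2[1])
    } else {
      prior <- estimate_variance_prior(s2, fit$df_resid)
    }
  } else if (prior_df == 0) {
    prior <- list(d0 = 0, s0_2 = NA_real_)
  } else if (is.infinite(prior_df)) {
    prior <- estimate_variance_prior(s2, fit$df_resid)
    prior$d0 <- Inf
  } else {
    prior <- estimate_variance_prior(s2, fit$df_resid)
    prior$d0 <- prior_df
  }
  s2_post <- if (prior$d0 == 0) s2 else
    posterior_variance(s2, fit$df_resid, prior$d0, prior$s0_2)
  df_total <- fit$df_resid + ifelse(is.infinite(prior$d0), Inf, prior$d0)
  tstat <- logfc / sqrt(u2 * s2_post)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  q <- bh_fdr(p)
  res <- data.frame(region_id = rownames(logged),
                    avg_log2 = rowMeans(logged),
                    logfc = logfc, t = tstat, p_value = p, fdr = q,
                    neg_log10_fdr = -log10(pmax(q, .Machine$double.xmin)),
                    neg_log10_p = -log10(pmax(p, .Machine$double.xmin)),
                    s2 = s2, s2_post = s2_post,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, d0 = prior$d0, s0_2 = prior$s0_2,
            df_resid = fit$df_resid, contrast = contrast,
            class = c("DiffResult", "data.frame"))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_i = min over j with p_(j) >= p_(i) of (p_(j) * m / j)`, capped at 1.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of adjusted values (monotone non-decreasing in p-rank).
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / seq(m, 1)))[ro]
}

#' Concordance of two FDR-thresholded id lists
#'
#' @param ids_a,ids_b character vectors of significant ids from two
#'   analyses over a comparable id universe.
#' @return list with `shared` (size of the intersection), `fraction`
#'   (shared / size of the smaller list; 0 with `defined = FALSE` when a
#'   list is empty), and `defined`.
#' @export
list_concordance <- function(ids_a, ids_b) {
  shared <- length(intersect(ids_a, ids_b))
  if (length(ids_a) == 0 || length(ids_b) == 0)
    return(list(shared = shared, fraction = 0, defined = FALSE))
  list(shared = shared,
       fraction = shared / min(length(ids_a), length(ids_b)),
       defined = TRUE)
}

#' Write a DiffResult as TSV (volcano-ready columns included)
#' @param result a `DiffResult` from [moderated_test()].
#' @param path output path.
#' @export
write_diff_result <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
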