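#' Per-reference fragment fractions per sample
#'
#' For each sample's fragment set, the fraction of total fragments
#' carrying each reference label (nuclear, mito, contaminant, ...).
#' Fractions sum to 1 when every fragment carries a label.
#'
#' @param fragment_sets named list of [fragment_set()]s (one per sample).
#' @param temperatures optional numeric vector of incubation temperatures
#'   (degC) per sample; taken from each set's metadata when absent.
#' @return data.frame of class `ContaminationProfile`: `sample`,
#'   `temperature`, one column per reference label.
#' @export
reference_fractions <- function(fragment_sets, temperatures = NULL) {
  labels <- sort(unique(unlist(lapply(fragment_sets, function(fs) fs$reference))))
  rows <- lapply(seq_along(fragment_sets), function(i) {
    fs <- fragment_sets[[i]]
    if (nrow(fs) == 0) stop("sample with zero fragments", call. = FALSE)
    tab <- table(factor(fs$reference, levels = labels))
    tmp <- if (!is.null(temperatures)) temperatures[i] else
      attr(fs, "metadata")$temperature %||% NA_real_
    cbind(data.frame(sample = attr(fs, "sample_id") %||% names(fragment_sets)[i],
                     temperature = tmp, stringsAsFactors = FALSE),
          as.data.frame.matrix(t(as.matrix(tab / nrow(fs)))))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ContaminationProfile", "data.frame")
  out
}

#' Anti-correlation between two reference fractions across samples
#'
#' Least-squares fit of the `label_y` fraction on the `label_x` fraction
#' across samples; under PCR competition between fixed nuclear DNA and
#' unfixed contaminant DNA the slope is negative with R^2 near 1.
#'
#' @param profiles a `ContaminationProfile` (e.g. from
#'   [reference_fractions()] or [simulate_contamination_profiles()]).
#' @param label_x,label_y column names of the two fractions.
#' @return list with `slope`, `intercept` and `r_squared`.
#' @export
anticorrelation <- function(profiles, label_x = "nuclear",
                            label_y = "contaminant") {
  if (nrow(profiles) < 3) stop("need at least 3 samples", call. = FALSE)
  x <- profiles[[label_x]]
  y <- profiles[[label_y]]
  if (is.null(x) || is.null(y)) stop("unknown reference label", call. = FALSE)
  if (stats::var(x) == 0) stop("constant x fraction; slope undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # summary() warns on an essentially perfect fit; R^2 = 1 is meaningful here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Fit the Arrhenius model to a temperature-recovery series
#'
#' Least squares of the transformed recovered fraction against reciprocal
#' absolute temperature (`T_Kelvin = T_degC + 273.15`). With
#' `transform = "log"` the response is `ln(fraction)`, matching the
#' conventional Arrhenius plot of recovery; with `transform = "logit"`
#' the response is `ln(f / (1 - f))`, which is exactly linear in `1/T`
#' under the competition model `f = k / (k + c)` for any competitor rate
#' `c`, making it the appropriate choice when the observable is a
#' fraction of a competitive pool.
#'
#' @param temperature temperatures in degC (> -273.15).
#' @param fraction recovered fractions (in `(0, 1]` for log; `(0, 1)` for
#'   logit).
#' @param transform `"log"` (default) or `"logit"`.
#' @return An `ArrheniusFit`: list with `lnA` (intercept), `slope`
#'   (= -Ea/R, Kelvin), `r_squared`, and the fitted `points`
#'   (`inv_T_kelvin`, `response`).
#' @export
fit_arrhenius <- function(temperature, fraction,
                          transform = c("log", "logit")) {
  transform <- match.arg(transform)
  if (length(temperature) < 2) stop("need at least 2 points", call. = FALSE)
  if (any(temperature <= -273.15))
    stop("temperature must exceed absolute zero (-273.15 degC)", call. = FALSE)
  if (any(fraction <= 0))
    stop("fractions must be positive (log undefined)", call. = FALSE)
  if (transform == "logit" && any(fraction >= 1))
    stop("logit transform requires fractions < 1", call. = FALSE)
  invT <- 1 / (temperature + 273.15)
  y <- if (transform == "log") log(fraction) else log(fraction / (1 - fraction))
  fit <- stats::lm(y ~ invT)
  r2 <- if (length(temperature) == 2) 1 else
    suppressWarnings(summary(fit)$r.squared)
  structure(list(lnA = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 transform = transform,
                 points = data.frame(inv_T_kelvin = invT, response = y)),
            class = "ArrheniusFit")
}

#' @export
print.ArrheniusFit <- function(x, ...) {
  cat(sprintf("ArrheniusFit (%s): lnA = %.3f, slope (-Ea/R) = %.1f K, R^2 = %.4f\n",
              x$transform, x$lnA, x$slope, x$r_squared))
  invisible(x)
}

#' Write contamination profiles as TSV
#' @param profiles a `ContaminationProfile`.
#' @param path output path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(as.data.frame(profiles), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
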