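# Per-element sigmoidal IO regression, R^2 maps, masking and hotspot
# extraction. The numerical core is a bounded multi-start
# Levenberg-Marquardt in C++ (src/sigmoid_fit.cpp); all randomness
# (start jitter) is drawn under a caller-supplied seed.

#' Sigmoidal input-output curve
#'
#' `yhat = y0 + (a - y0) / (1 + exp(-r (x - x0)))`: floor `y0` (mV),
#' saturation `a` (mV), slope `r` (per V/m), turning point `x0` (V/m).
#' Evaluation is overflow-safe for large `|r (x - x0)|`.
#'
#' @param params list or named vector with `y0`, `a`, `r`, `x0`.
#' @param x field quantity values, V/m.
#' @return predicted MEP amplitudes, mV.
#' @export
sigmoid_predict <- function(params, x) {
  p <- as.list(params)
  p$y0 + (p$a - p$y0) * stats::plogis(p$r * (x - p$x0))
}

#' Fitting configuration for the sigmoidal regression
#'
#' @param n_starts number of multi-start initializations (a data-driven
#'   heuristic start plus `n_starts - 1` jittered variants).
#' @param seed seed for the start jitter (fits are bit-reproducible).
#' @param jitter_sd log-scale s.d. of the multiplicative start jitter.
#' @param max_iter Levenberg-Marquardt iteration cap per start.
#' @param ftol relative SSE decrease declaring convergence.
#' @param r_max upper bound on the slope parameter.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 5, seed = 1, jitter_sd = 0.4,
                       max_iter = 150, ftol = 1e-10, r_max = 1e3) {
  structure(list(n_starts = n_starts, seed = seed, jitter_sd = jitter_sd,
                 max_iter = max_iter, ftol = ftol, r_max = r_max),
            class = "fit_config")
}

# jitter factors: first row is the unjittered heuristic start
start_jitter <- function(config) {
  k <- config$n_starts
  if (k < 1) stop("n_starts must be >= 1")
  j <- matrix(1, k, 4)
  if (k > 1)
    j[-1, ] <- with_seed(config$seed,
                         matrix(exp(rnorm(4 * (k - 1), 0, config$jitter_sd)),
                                k - 1, 4))
  j
}

# batch fit over columns of X (n_pulses x n_elements); warm is an
# optional n_elements x 4 matrix of extra starts
fit_batch <- function(X, y, config = fit_config(), warm = NULL) {
  .cpp_fit_sigmoid_batch(X, y, start_jitter(config), warm,
                         config$r_max, config$max_iter, config$ftol)
}

#' Fit the sigmoidal IO curve to one element
#'
#' Bounded multi-start least squares with
#' `y0 in [0, median(y)]`, `a in [median(y), 2 max(y)]`, `r > 0`,
#' `x0 in [min(x), max(x)]`. With fewer than 10 pulses the fit is
#' returned but flagged unreliable; constant `x` yields a degenerate
#' flag with `r2 = 0`.
#'
#' @param x field quantity per pulse, V/m.
#' @param y MEP amplitudes per pulse, mV.
#' @param config a [fit_config()].
#' @return list of class `sigmoid_fit` with `y0`, `a`, `r`, `x0`, `r2`,
#'   `sse`, `converged`, `reliable`, `n`.
#' @export
fit_sigmoid <- function(x, y, config = fit_config()) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  f <- unname(fit_batch(matrix(as.numeric(x), ncol = 1), as.numeric(y),
                        config))
  structure(list(y0 = f[1], a = f[2], r = f[3], x0 = f[4], r2 = f[6],
                 sse = f[5], converged = f[7] == 1,
                 reliable = length(x) >= 10, n = length(x)),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "sigmoid_fit: y0=%.4g a=%.4g r=%.4g x0=%.4g  R2=%.4f%s (n=%d)\n",
    x$y0, x$a, x$r, x$x0, x$r2,
    if (!x$converged) " [not converged]" else "", x$n))
  invisible(x)
}

#' Coefficient of determination from residual variance
#'
#' `R2 = 1 - VAR(y - yhat) / VAR(y)`. Both variances use the same
#' estimator, so the population-vs-sample convention cancels; values may
#' be negative for fits worse than a constant and any constant predictor
#' scores exactly 0 (variance is shift-invariant).
#'
#' @param y observed values.
#' @param yhat fitted values.
#' @return R-squared.
#' @export
r2_score <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  vy <- var(y)
  if (!is.finite(vy) || vy == 0) stop("VAR(y) must be > 0")
  1 - var(y - yhat) / vy
}

#' Localization configuration
#'
#' @param e_min field-exposure threshold, V/m: an element is analyzable
#'   only if enough pulses delivered `|E| > e_min` there.
#' @param p_min minimum fraction of pulses exceeding `e_min` (the
#'   "at least 25% of trials above 40 V/m" rule).
#' @param roi_label anatomical label elements must carry to be eligible
#'   for the hotspot (`NULL` disables the label restriction).
#' @param fit a [fit_config()].
#' @return list of class `localize_config`.
#' @export
localize_config <- function(e_min = 40, p_min = 0.25,
                            roi_label = "precentral", fit = fit_config()) {
  structure(list(e_min = e_min, p_min = p_min, roi_label = roi_label,
                 fit = fit),
            class = "localize_config")
}

#' Per-element sigmoidal regression and R^2 hotspot map
#'
#' Fits the sigmoidal IO curve independently at every masked element and
#' returns the R^2 map with its hotspot (masked argmax of R^2; ties
#' break to the lowest element id). The validity mask keeps elements
#' that (i) carry the ROI label, (ii) had `|E| > e_min` in at least a
#' fraction `p_min` of pulses, and (iii) have finite quantity values for
#' all pulses (zero-field elements with undefined polar angle drop out
#' here).
#'
#' @param x `n_pulses x m` quantity matrix (from [quantity_map()]).
#' @param meps MEP amplitudes per pulse, mV.
#' @param emag `n_pulses x m` magnitude matrix used for the exposure
#'   mask (defaults to `x`, which is exact for the magnitude model).
#' @param labels per-element anatomical labels (or `NULL`).
#' @param config a [localize_config()].
#' @param mask optional logical vector overriding the computed mask
#'   (used to freeze the mask across convergence subsamples).
#' @param warm optional `m x 4` matrix of warm-start parameters.
#' @return object of class `r2_map`: `fits` (m x 7 matrix), `r2`,
#'   `mask`, `hotspot`, `model`, `n_pulses`.
#' @export
localize <- function(x, meps, emag = x, labels = NULL,
                     config = localize_config(), mask = NULL, warm = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (length(meps) != n) stop("quantity map and MEPs are not pulse-aligned")
  if (is.null(mask)) {
    mask <- rep(TRUE, m)
    if (!is.null(labels) && !is.null(config$roi_label)) {
      if (length(labels) != m) stop("labels length must equal element count")
      mask <- mask & (labels == config$roi_label)
    }
    coverage <- colMeans(emag > config$e_min)
    mask <- mask & (coverage >= config$p_min - 1e-12)
    mask <- mask & apply(is.finite(x), 2, all)
  } else {
    if (length(mask) != m) stop("mask length must equal element count")
  }
  if (!any(mask)) {
    stop(sprintf(paste0(
      "empty element mask: no element satisfies the ROI label and the ",
      "exposure rule (|E| > %g V/m in >= %g%% of %d pulses)"),
      config$e_min, 100 * config$p_min, n))
  }
  fits <- matrix(NA_real_, m, 7,
                 dimnames = list(NULL, c("y0", "a", "r", "x0", "sse", "r2",
                                         "converged")))
  idx <- which(mask)
  fits[idx, ] <- fit_batch(x[, idx, drop = FALSE], as.numeric(meps),
                           config$fit,
                           if (is.null(warm)) NULL
                           else warm[idx, , drop = FALSE])
  r2 <- fits[, "r2"]
  hotspot <- idx[which.max(r2[idx])] # which.max takes the first maximum
  structure(list(fits = fits, r2 = r2, mask = mask, hotspot = hotspot,
                 model = attr(x, "model") %||% "unknown", n_pulses = n),
            class = "r2_map")
}

#' @export
print.r2_map <- function(x, ...) {
  cat(sprintf(
    "r2_map (%s model): %d/%d elements masked in, hotspot element %d (R2 = %.3f), n = %d pulses\n",
    x$model, sum(x$mask), length(x$mask), x$hotspot, x$r2[x$hotspot],
    x$n_pulses))
  invisible(x)
}

#' Compare peak R^2 values across models (repeated measures)
#'
#' Friedman test across models on the per-subject R^2 peaks, followed by
#' Holm-corrected pairwise Wilcoxon signed-rank tests.
#'
#' @param peaks numeric matrix, subjects x models (column names are the
#'   model tags).
#' @return list with `friedman` (statistic, df, p) and `pairwise`
#'   data frame (V statistic, raw and Holm-adjusted p).
#' @export
compare_peak_r2 <- function(peaks) {
  peaks <- as.matrix(peaks)
  if (nrow(peaks) < 3) stop("need >= 3 subjects")
  if (any(!is.finite(peaks))) stop("unequal subject sets across models")
  fr <- friedman_safe(peaks)
  combs <- utils::combn(ncol(peaks), 2)
  pw <- data.frame(
    a = colnames(peaks)[combs[1, ]] %||% combs[1, ],
    b = colnames(peaks)[combs[2, ]] %||% combs[2, ],
    statistic = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(combs))) {
    d <- peaks[, combs[1, i]] - peaks[, combs[2, i]]
    if (all(d == 0)) { # degenerate: identical models
      pw$statistic[i] <- 0
      pw$p[i] <- 1
    } else {
      wt <- suppressWarnings(wilcox.test(d, exact = FALSE))
      pw$statistic[i] <- unname(wt$statistic)
      pw$p[i] <- wt$p.value
    }
  }
  pw$p_holm <- holm_adjust(pw$p)
  list(friedman = fr, pairwise = pw)
}

# Friedman test tolerating the fully tied case (statistic 0, p 1),
# where stats::friedman.test's tie correction divides by zero
friedman_safe <- function(mat) {
  if (all(apply(mat, 1, function(r) max(r) == min(r))))
    return(list(statistic = 0, df = ncol(mat) - 1, p = 1))
  fr <- friedman.test(mat)
  list(statistic = unname(fr$statistic), df = unname(fr$parameter),
       p = fr$p.value)
}
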