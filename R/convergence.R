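# Pulse-subsampling convergence analysis: NRMSD map similarity and
# geodesic hotspot stability as functions of the number of pulses.

#' Normalized root-mean-square deviation between two R^2 maps
#'
#' `sqrt(mean((current - reference)^2)) / (max(ref) - min(ref))`:
#' root-mean-square element-wise deviation normalized by the reference
#' map's range. Shift-invariant (adding a constant to both maps changes
#' nothing) and zero iff the maps are equal.
#'
#' @param current,reference numeric vectors over the same elements.
#' @return unitless NRMSD.
#' @export
nrmsd <- function(current, reference) {
  if (length(current) != length(reference))
    stop("maps must cover the same elements")
  rng <- max(reference) - min(reference)
  if (rng <= 0) stop("reference map is constant: NRMSD undefined")
  sqrt(mean((current - reference)^2)) / rng
}

#' Enumerate a convergence schedule
#'
#' Pulse counts and total number of R^2 maps implied by a sequential
#' analysis from `n_min` to `n_max` pulses repeated over `n_rand`
#' randomized orderings. With the full protocol (10 to 800, 100
#' randomizations, step 1) this enumerates 79100 maps.
#'
#' @param n_min,n_max first and last pulse counts.
#' @param n_step schedule step (1 = every pulse count).
#' @param n_rand number of randomized pulse orderings.
#' @return list with `n_values`, `n_rand`, `n_maps`.
#' @export
convergence_schedule <- function(n_min = 10, n_max = 800, n_step = 1,
                                 n_rand = 100) {
  if (n_max < n_min) stop("n_max must be >= n_min")
  n_values <- seq.int(n_min, n_max, by = n_step)
  list(n_values = n_values, n_rand = as.integer(n_rand),
       n_maps = length(n_values) * as.integer(n_rand))
}

#' Sequential localizations over randomized pulse orderings
#'
#' For each of `n_rand` randomized pulse orderings, localizes on the
#' first `n` pulses for every `n` in the schedule and records, per map:
#' NRMSD against the full-N reference map and against the previous
#' schedule entry, and the geodesic hotspot distance against both. The
#' element mask is frozen from the full-N reference so maps are compared
#' over identical elements. After the first schedule entry, fits are
#' warm-started from the previous `n` within each ordering (heuristic
#' start + warm start instead of the full jittered multi-start); the
#' resulting maps agree with cold-start localization to well under the
#' 5% NRMSD convergence criterion (asserted in the test suite).
#'
#' @param x `n_pulses x m` quantity matrix.
#' @param meps MEP amplitudes per pulse, mV.
#' @param emag magnitude matrix for the exposure mask (see [localize()]).
#' @param labels per-element labels or `NULL`.
#' @param mesh the layer [surface_mesh()] (for geodesic distances).
#' @param n_min,n_max,n_step,n_rand schedule, see
#'   [convergence_schedule()]; `n_max` defaults to all pulses.
#' @param seed master seed for the orderings.
#' @param config a [localize_config()].
#' @param reference optional precomputed full-N [localize()] result.
#' @return list of class `convergence_traces`: `traces` (data frame with
#'   columns `randomization`, `n`, `nrmsd_ref`, `nrmsd_prev`,
#'   `dist_ref_mm`, `dist_prev_mm`), `reference`, `schedule`, `model`.
#' @export
sequential_maps <- function(x, meps, emag = x, labels = NULL, mesh,
                            n_min = 10, n_max = nrow(x), n_step = 1,
                            n_rand = 100, seed = 1,
                            config = localize_config(), reference = NULL) {
  x <- as.matrix(x)
  n_pulses <- nrow(x)
  if (n_max > n_pulses) stop("n_max exceeds the number of pulses")
  sched <- convergence_schedule(n_min, n_max, n_step, n_rand)
  if (is.null(reference))
    reference <- localize(x, meps, emag, labels, config)
  mask <- reference$mask
  idx <- which(mask)
  ref_r2 <- reference$r2[idx]

  graph <- mesh_graph(mesh)
  # geodesic distances among all maskable elements (hotspots live there)
  dmat <- geodesic_distance_matrix(mesh, idx, idx, graph)
  pos_of <- match(seq_len(ncol(x)), idx)

  # after the first schedule entry the previous solution seeds the fit,
  # so the jittered multi-start collapses to the heuristic start + warm
  config_warm <- config
  config_warm$fit$n_starts <- 1

  rows <- vector("list", n_rand)
  for (r in seq_len(n_rand)) {
    perm <- with_seed(derive_seed(seed, paste0("ordering", r)),
                      sample.int(n_pulses))
    warm <- NULL
    prev_r2 <- NULL
    prev_hot <- NA_integer_
    out <- data.frame(randomization = r, n = sched$n_values,
                      nrmsd_ref = NA_real_, nrmsd_prev = NA_real_,
                      dist_ref_mm = NA_real_, dist_prev_mm = NA_real_,
                      hotspot = NA_integer_, hotspot_prev = NA_integer_)
    for (k in seq_along(sched$n_values)) {
      n <- sched$n_values[k]
      take <- perm[seq_len(n)]
      map <- localize(x[take, , drop = FALSE], meps[take],
                      emag[take, , drop = FALSE], labels,
                      if (is.null(warm)) config else config_warm,
                      mask = mask, warm = warm)
      warm <- map$fits[, c("y0", "a", "r", "x0"), drop = FALSE]
      cur_r2 <- map$r2[idx]
      hot <- map$hotspot
      out$nrmsd_ref[k] <- nrmsd(cur_r2, ref_r2)
      out$dist_ref_mm[k] <- dmat[pos_of[hot], pos_of[reference$hotspot]]
      out$hotspot[k] <- hot
      if (k > 1) {
        out$nrmsd_prev[k] <- nrmsd(cur_r2, prev_r2)
        out$dist_prev_mm[k] <- dmat[pos_of[hot], pos_of[prev_hot]]
        out$hotspot_prev[k] <- prev_hot
      }
      prev_r2 <- cur_r2
      prev_hot <- hot
    }
    rows[[r]] <- out
  }
  structure(list(traces = do.call(rbind, rows), reference = reference,
                 schedule = sched, model = reference$model),
            class = "convergence_traces")
}

#' Minimum pulse count meeting a convergence criterion
#'
#' In `"sustained"` mode (default), the smallest scheduled `n` such that
#' the metric stays at or below `threshold` for every scheduled
#' `n' >= n`; in `"first"` mode, the first crossing. Leading `NA`
#' entries (the vs-previous metrics are undefined at the first schedule
#' entry) are ignored. If the criterion is never met the sentinel `NA`
#' is returned with attribute `converged = FALSE`.
#'
#' @param trace data frame for a single randomization (columns `n` and
#'   the metric).
#' @param metric metric column name, e.g. `"nrmsd_ref"` or
#'   `"dist_ref_mm"`.
#' @param threshold convergence threshold (0.05 for NRMSD, 1 mm for the
#'   hotspot distance).
#' @param mode `"sustained"` or `"first"`.
#' @return integer pulse count (or `NA` if never converged).
#' @export
min_pulses_to_converge <- function(trace, metric, threshold,
                                   mode = c("sustained", "first")) {
  mode <- match.arg(mode)
  if (!metric %in% names(trace)) stop("trace does not cover metric ", metric)
  o <- order(trace$n)
  n <- trace$n[o]
  v <- trace[[metric]][o]
  keep <- !is.na(v)
  n <- n[keep]
  v <- v[keep]
  if (!length(n)) return(structure(NA_integer_, converged = FALSE))
  ok <- v <= threshold
  hit <- if (mode == "first") {
    which(ok)[1]
  } else {
    below_all <- rev(cumprod(rev(ok))) == 1
    which(below_all)[1]
  }
  if (is.na(hit)) structure(NA_integer_, converged = FALSE)
  else structure(as.integer(n[hit]), converged = TRUE)
}

#' Summarize convergence traces into mean minimum pulse counts
#'
#' Applies [min_pulses_to_converge()] per randomization and metric and
#' averages across randomizations (unconverged randomizations are
#' excluded from the mean and counted separately).
#'
#' @param traces a `convergence_traces` object (or its `traces` frame).
#' @param nrmsd_threshold,dist_threshold convergence thresholds
#'   (defaults 5% and 1 mm).
#' @param mode passed to [min_pulses_to_converge()].
#' @return data frame with one row per metric: mean, median, number of
#'   converged randomizations.
#' @export
convergence_summary <- function(traces, nrmsd_threshold = 0.05,
                                dist_threshold = 1,
                                mode = c("sustained", "first")) {
  mode <- match.arg(mode)
  df <- if (inherits(traces, "convergence_traces")) traces$traces else traces
  metrics <- c(nrmsd_ref = nrmsd_threshold, nrmsd_prev = nrmsd_threshold,
               dist_ref_mm = dist_threshold, dist_prev_mm = dist_threshold)
  res <- lapply(names(metrics), function(mname) {
    mins <- vapply(split(df, df$randomization), function(tr)
      as.numeric(min_pulses_to_converge(tr, mname, metrics[[mname]], mode)),
      0)
    data.frame(metric = mname, threshold = metrics[[mname]],
               mean_min_pulses = mean(mins, na.rm = TRUE),
               median_min_pulses = median(mins, na.rm = TRUE),
               n_converged = sum(!is.na(mins)),
               n_randomizations = length(mins))
  })
  do.call(rbind, res)
}

#' Conover post-hoc test after a Friedman test
#'
#' All-pairs Conover-Iman comparisons on the within-block ranks of a
#' subjects x treatments matrix, with multiple-comparison correction
#' (Bonferroni by default, matching common usage after Friedman).
#'
#' @param mat numeric matrix, subjects (blocks) x treatments.
#' @param p_adjust_method passed to [stats::p.adjust()].
#' @return data frame of pairwise t statistics, df and adjusted p.
#' @export
conover_posthoc <- function(mat, p_adjust_method = "bonferroni") {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2 || k < 2) stop("need >= 2 blocks and >= 2 treatments")
  Rij <- t(apply(mat, 1, rank))
  Rj <- colSums(Rij)
  A <- sum(Rij^2)
  B <- sum(Rj^2) / n
  dfree <- (n - 1) * (k - 1)
  denom <- sqrt(2 * n * (A - B) / dfree)
  combs <- utils::combn(k, 2)
  nm <- colnames(mat) %||% as.character(seq_len(k))
  out <- data.frame(a = nm[combs[1, ]], b = nm[combs[2, ]],
                    statistic = NA_real_, df = dfree, p = NA_real_)
  for (i in seq_len(ncol(combs))) {
    if (denom == 0) { # identical ranks in every block
      out$statistic[i] <- 0
      out$p[i] <- 1
    } else {
      t <- (Rj[combs[1, i]] - Rj[combs[2, i]]) / denom
      out$statistic[i] <- t
      out$p[i] <- 2 * pt(-abs(t), dfree)
    }
  }
  out$p_adj <- p.adjust(out$p, method = p_adjust_method)
  out
}

#' Compare convergence pulse counts across models
#'
#' Friedman test on the per-subject minimum pulse counts across models,
#' followed by Conover post-hoc pairwise comparisons.
#'
#' @param counts numeric matrix, subjects x models.
#' @param p_adjust_method correction for the post-hoc pairs.
#' @return list with `friedman` and `posthoc`.
#' @export
compare_convergence <- function(counts, p_adjust_method = "bonferroni") {
  counts <- as.matrix(counts)
  if (nrow(counts) < 3) stop("need >= 3 subjects")
  if (any(!is.finite(counts)))
    stop("missing cells: models/subjects are not aligned")
  list(friedman = friedman_safe(counts),
       posthoc = conover_posthoc(counts, p_adjust_method))
}
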