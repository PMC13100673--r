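#' Coil placement
#'
#' A TMS coil placement: center position (mm), right-handed orthonormal
#' axes (`y_axis` is the current-direction reference, `z_axis` the coil
#' normal pointing toward the head), and a dimensionless intensity
#' multiplier on the induced field (proxy for stimulator output times
#' pulse rate of change).
#'
#' @param position numeric length-3, mm.
#' @param x_axis,y_axis,z_axis orthonormal unit vectors (checked to 1e-9).
#' @param intensity positive scalar field multiplier.
#' @return an object of class `coil_placement`.
#' @export
coil_placement <- function(position, x_axis, y_axis, z_axis, intensity = 1) {
  A <- rbind(x_axis, y_axis, z_axis)
  if (max(abs(A %*% t(A) - diag(3))) > 1e-9)
    stop("coil axes must be orthonormal (within 1e-9)")
  if (!is.numeric(intensity) || intensity <= 0)
    stop("intensity must be > 0")
  structure(list(position = as.numeric(position),
                 x_axis = as.numeric(x_axis), y_axis = as.numeric(y_axis),
                 z_axis = as.numeric(z_axis),
                 intensity = as.numeric(intensity)),
            class = "coil_placement")
}

#' @export
print.coil_placement <- function(x, ...) {
  cat(sprintf("coil_placement @ (%.1f, %.1f, %.1f) mm, intensity %.3g\n",
              x$position[1], x$position[2], x$position[3], x$intensity))
  invisible(x)
}

#' Synthetic gyral phantom
#'
#' Builds a sinusoidal gyral ribbon as a stand-in for a precentral-gyrus
#' head model: the GM (pial-side) surface is `z = A cos(2 pi x / lambda)`
#' so that a gyral crown lies at `x = 0`, the WM surface is offset inward
#' by the cortical thickness along the local surface normal (preserving
#' vertex correspondence), a central band of elements is labeled
#' `"precentral"`, and a planar scalp sits above the ribbon. A small
#' seeded in-plane vertex jitter breaks the regular-lattice symmetry of
#' the triangulation.
#'
#' Phantom anatomical conventions: `+x` is anterior (across the gyrus),
#' `+y` superior (along the gyrus), `+z` points from cortex to scalp.
#'
#' @param n_x,n_y vertices along x and y (>= 4); element count is
#'   `2 (n_x - 1)(n_y - 1)`.
#' @param amplitude gyral fold amplitude, mm (0 gives flat sheets).
#' @param thickness cortical thickness (GM-to-WM offset), mm.
#' @param extent c(x, y) sheet extent, mm.
#' @param wavelength gyral wavelength, mm.
#' @param scalp_offset scalp plane height above the highest crown, mm.
#' @param band_halfwidth half-width in x of the `"precentral"` label
#'   band, mm.
#' @param jitter in-plane vertex jitter standard deviation, mm.
#' @param seed integer seed for the jitter.
#' @return list of class `gyral_phantom` with elements `stack`
#'   (a [layer_stack()]), `scalp` (a [surface_mesh()]), and `params`.
#' @export
gyral_phantom <- function(n_x = 29, n_y = 29, amplitude = 4, thickness = 2.5,
                          extent = c(60, 40), wavelength = 20,
                          scalp_offset = 15, band_halfwidth = 7.5,
                          jitter = 0.15, seed = 1) {
  if (n_x < 4 || n_y < 4) stop("n_x and n_y must be >= 4")
  if (thickness <= 0) stop("thickness must be > 0")
  xs <- seq(-extent[1] / 2, extent[1] / 2, length.out = n_x)
  ys <- seq(-extent[2] / 2, extent[2] / 2, length.out = n_y)
  g <- expand.grid(x = xs, y = ys)
  if (jitter > 0) {
    with_seed(seed, {
      dx <- rnorm(nrow(g), 0, jitter)
      dy <- rnorm(nrow(g), 0, jitter)
    })
    # keep boundary vertices on the boundary
    interior_x <- g$x > min(xs) & g$x < max(xs)
    interior_y <- g$y > min(ys) & g$y < max(ys)
    g$x <- g$x + dx * interior_x
    g$y <- g$y + dy * interior_y
  }
  k <- 2 * pi / wavelength
  z <- amplitude * cos(k * g$x)
  dzdx <- -amplitude * k * sin(k * g$x)
  # inward unit normal of the GM sheet: -( -f'(x), 0, 1 ) / sqrt(1 + f'^2)
  nrm <- cbind(-dzdx, 0, 1) / sqrt(1 + dzdx^2)
  gm_v <- cbind(g$x, g$y, z)
  wm_v <- gm_v - thickness * nrm

  idx <- function(i, j) (j - 1L) * n_x + i
  i <- rep(seq_len(n_x - 1L), n_y - 1L)
  j <- rep(seq_len(n_y - 1L), each = n_x - 1L)
  t1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  t2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  tri <- rbind(t1, t2)

  gm <- surface_mesh(gm_v, tri)
  cen <- element_centroids(gm)
  labels <- ifelse(abs(cen[, 1]) <= band_halfwidth, "precentral", "other")
  gm <- surface_mesh(gm_v, tri, labels)
  wm <- surface_mesh(wm_v, tri, labels)
  stack <- layer_stack(gm, wm)

  z_scalp <- amplitude + scalp_offset
  sxs <- seq(-extent[1] / 2 - 60, extent[1] / 2 + 60, by = 10)
  sys <- seq(-extent[2] / 2 - 60, extent[2] / 2 + 60, by = 10)
  sg <- expand.grid(x = sxs, y = sys)
  sn_x <- length(sxs)
  sidx <- function(i, j) (j - 1L) * sn_x + i
  si <- rep(seq_len(sn_x - 1L), length(sys) - 1L)
  sj <- rep(seq_len(length(sys) - 1L), each = sn_x - 1L)
  stri <- rbind(cbind(sidx(si, sj), sidx(si + 1L, sj), sidx(si + 1L, sj + 1L)),
                cbind(sidx(si, sj), sidx(si + 1L, sj + 1L), sidx(si, sj + 1L)))
  scalp <- surface_mesh(cbind(sg$x, sg$y, z_scalp), stri)

  structure(list(stack = stack, scalp = scalp,
                 params = list(n_x = n_x, n_y = n_y, amplitude = amplitude,
                               thickness = thickness, extent = extent,
                               wavelength = wavelength,
                               scalp_offset = scalp_offset,
                               band_halfwidth = band_halfwidth,
                               jitter = jitter, seed = seed,
                               z_scalp = z_scalp)),
            class = "gyral_phantom")
}

#' @export
print.gyral_phantom <- function(x, ...) {
  cat("gyral_phantom:", n_elements(x$stack$gm), "elements,",
      sum(x$stack$gm$labels == "precentral"), "in the precentral band\n")
  invisible(x)
}

#' Ground-truth element of a phantom
#'
#' Picks the simulated cortical origin of the MEPs inside the
#' `"precentral"` band. The default `"rim"` places it halfway down the
#' central crown's shoulder (|x| near an eighth of the gyral
#' wavelength, nearest y = 0), where hand-muscle representations sit on
#' real precentral gyri and where the somato-dendritic axis is tilted,
#' so the field direction at the origin varies across coil placements
#' and the direction-sensitive response models are identifiable.
#' `"crown"` picks the element nearest the crown center instead; there
#' the polar angle is nearly constant and the effective-field model
#' degenerates to a rescaled magnitude model.
#'
#' @param phantom a [gyral_phantom()].
#' @param location `"rim"` (default) or `"crown"`.
#' @return element id.
#' @export
phantom_true_element <- function(phantom, location = c("rim", "crown")) {
  location <- match.arg(location)
  cen <- element_centroids(phantom$stack$gm)
  cand <- which(phantom$stack$gm$labels == "precentral")
  x_target <- if (location == "crown") 0 else phantom$params$wavelength / 8
  cand[which.min((abs(cen[cand, 1]) - x_target)^2 + cen[cand, 2]^2)]
}

#' Reference (optimal-like) coil placement over the phantom
#'
#' Coil on the scalp directly above the central crown, normal pointing
#' down toward the cortex, current-direction axis rotated `angle_deg`
#' from the anterior (+x) axis in the scalp plane (default 45 degrees,
#' the usual posterior-anterior 45-degree motor-cortex orientation).
#'
#' @param phantom a [gyral_phantom()].
#' @param angle_deg in-plane orientation of the y (current) axis.
#' @param intensity field intensity multiplier.
#' @return a [coil_placement()].
#' @export
reference_placement <- function(phantom, angle_deg = 45, intensity = 1) {
  th <- angle_deg * pi / 180
  y <- c(cos(th), sin(th), 0)
  z <- c(0, 0, -1)
  x <- cross3(y, z)
  coil_placement(c(0, 0, phantom$params$z_scalp), x, y, z, intensity)
}

#' Random coil placements around a reference
#'
#' Positions uniform on the scalp disc of the given radius around the
#' reference position; orientation is the reference orientation rotated
#' about the coil normal by an angle uniform in
#' `[-max_angle, +max_angle]`. This reproduces the randomized mapping
#' protocol (3 cm radius, approximately +/- 60 degrees).
#'
#' @param reference a [coil_placement()].
#' @param n number of placements.
#' @param radius scatter radius, mm.
#' @param max_angle maximum in-plane rotation, degrees.
#' @param seed integer seed.
#' @param scalp optional scalp [surface_mesh()] to re-project positions.
#' @return list of [coil_placement()] objects.
#' @export
sample_coil_placements <- function(reference, n, radius = 30, max_angle = 60,
                                   seed = 1, scalp = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (radius < 0) stop("radius must be >= 0")
  with_seed(seed, {
    rho <- radius * sqrt(runif(n))
    phi <- runif(n, 0, 2 * pi)
    ang <- runif(n, -max_angle, max_angle)
  })
  e1 <- reference$x_axis
  e2 <- reference$y_axis
  lapply(seq_len(n), function(i) {
    pos <- reference$position + rho[i] * (cos(phi[i]) * e1 + sin(phi[i]) * e2)
    if (!is.null(scalp)) pos <- project_to_scalp(pos, scalp)
    R <- rotation_about_axis(reference$z_axis, ang[i])
    coil_placement(pos,
                   as.numeric(R %*% reference$x_axis),
                   as.numeric(R %*% reference$y_axis),
                   reference$z_axis,
                   reference$intensity)
  })
}

#' Analytic figure-of-eight primary electric field
#'
#' Smooth, placement-dependent primary field from two opposed magnetic
#' dipoles offset `+/- wing` along the coil x axis with moments along the
#' coil normal:
#' `E(r) = intensity * scale * sum_j s_j (m x (r - p_j)) / |r - p_j|^3`,
#' `s = (+1, -1)`. The field decays with distance, rotates rigidly with
#' the coil, and points along the coil y (current) axis beneath the coil
#' center, mimicking figure-of-eight focality. It is a geometric test
#' field, not a physics substitute for a FEM solution.
#'
#' @param placement a [coil_placement()].
#' @param points `m x 3` matrix of evaluation points (element centroids),
#'   mm.
#' @param wing dipole offset from the coil center, mm.
#' @param scale field scale factor mapping the geometric kernel to V/m
#'   (see [calibrate_primary_scale()]).
#' @return `m x 3` matrix of E-field vectors, V/m.
#' @export
primary_efield <- function(placement, points, wing = 20, scale = 1) {
  pts <- if (is.null(dim(points))) matrix(points, 1, 3) else as.matrix(points)
  m <- placement$z_axis
  p1 <- placement$position + wing * placement$x_axis
  p2 <- placement$position - wing * placement$x_axis
  term <- function(p, sgn) {
    d <- sweep(pts, 2, p)
    r3 <- (rowSums(d^2))^1.5
    if (any(r3 < 1e-12))
      stop("evaluation point coincides with a dipole position")
    cx <- cbind(m[2] * d[, 3] - m[3] * d[, 2],
                m[3] * d[, 1] - m[1] * d[, 3],
                m[1] * d[, 2] - m[2] * d[, 1])
    sgn * cx / r3
  }
  placement$intensity * scale * (term(p1, 1) + term(p2, -1))
}

#' Calibrate the primary-field scale
#'
#' Returns the `scale` for [primary_efield()] such that the field
#' magnitude at `point` under `placement` (at intensity 1) equals
#' `target` V/m. Used to put the phantom's field range in a realistic
#' regime (around 100 V/m at the crown under the coil).
#'
#' @param placement a [coil_placement()].
#' @param point length-3 evaluation point, mm.
#' @param target desired |E| in V/m.
#' @param wing dipole offset, mm.
#' @return scalar scale factor.
#' @export
calibrate_primary_scale <- function(placement, point, target = 100,
                                    wing = 20) {
  p <- coil_placement(placement$position, placement$x_axis,
                      placement$y_axis, placement$z_axis, 1)
  e <- primary_efield(p, matrix(point, 1, 3), wing = wing, scale = 1)
  target / vec_norm(e[1, ])
}

#' Sigmoid ground truth for MEP generation
#'
#' Parameters of the sigmoidal input-output curve at the true cortical
#' element plus the multiplicative log-normal noise level. Defaults give
#' a 2 mV saturating FDI-like IO curve with a 0.02 mV noise floor and a
#' turning point at 60 V/m.
#'
#' @param true_element element id of the true cortical origin.
#' @param model generating quantity model: `"magnitude"`, `"cosine"` or
#'   `"neuron"`.
#' @param y0 floor amplitude, mV (measurement noise level).
#' @param a saturation amplitude, mV.
#' @param r sigmoid slope, per (V/m).
#' @param x0 turning point, V/m.
#' @param noise_sd_log standard deviation of the log-normal noise.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(true_element, model = "magnitude", y0 = 0.02,
                         a = 2, r = 0.1, x0 = 60, noise_sd_log = 0.3) {
  model <- match.arg(model, c("magnitude", "cosine", "neuron"))
  if (!(a > y0 && y0 >= 0)) stop("need a > y0 >= 0")
  if (r <= 0 || x0 <= 0) stop("need r > 0 and x0 > 0")
  structure(list(true_element = true_element, model = model,
                 y0 = y0, a = a, r = r, x0 = x0,
                 noise_sd_log = noise_sd_log),
            class = "ground_truth")
}

#' Draw MEP amplitudes from a sigmoid with log-normal noise
#'
#' `mep_i = sigmoid(x_i) * exp(eps_i)` with
#' `eps_i ~ N(0, noise_sd_log^2)`, floored at an independently drawn
#' noise floor `y0 * exp(eps'_i)` (MEPs are positive and right-skewed;
#' the log transform of the generated amplitudes is symmetric).
#'
#' @param truth a [ground_truth()].
#' @param x field quantity at the true element per pulse, V/m (>= 0).
#' @param seed integer seed.
#' @return numeric vector of MEP amplitudes, mV.
#' @export
generate_meps <- function(truth, x, seed = 1) {
  if (any(x < 0)) stop("x must be >= 0")
  n <- length(x)
  s <- sigmoid_predict(truth, x)
  if (truth$noise_sd_log == 0) return(s)
  with_seed(seed, {
    eps <- rnorm(n, 0, truth$noise_sd_log)
    eps_floor <- rnorm(n, 0, truth$noise_sd_log)
  })
  pmax(s * exp(eps), truth$y0 * exp(eps_floor))
}

#' Peak-to-peak MEP amplitude from an EMG trace
#'
#' Maximum minus minimum of the trace restricted to the post-pulse
#' window (default 18-35 ms at 4 kHz sampling, the standard FDI MEP
#' window).
#'
#' @param trace sampled EMG, mV; the first sample is at the TMS pulse
#'   (t = 0).
#' @param fs sampling rate, Hz.
#' @param window_ms c(lo, hi) window after the pulse, ms.
#' @return peak-to-peak amplitude, mV.
#' @export
mep_peak_to_peak <- function(trace, fs = 4000, window_ms = c(18, 35)) {
  t_ms <- (seq_along(trace) - 1) / fs * 1000
  if (max(t_ms) < window_ms[2])
    stop("trace does not cover the analysis window")
  w <- trace[t_ms >= window_ms[1] & t_ms <= window_ms[2]]
  max(w) - min(w)
}

#' Estimate the resting motor threshold of a simulated IO curve
#'
#' Scans an ascending intensity ladder and returns the lowest ladder
#' intensity at which at least `n_required` of `n_pulses` simulated MEPs
#' exceed `threshold_mv` (the 50 microvolt in 5-of-10 criterion).
#'
#' @param simulator function(intensity) returning one simulated MEP draw
#'   in mV; must be monotone in expectation.
#' @param seed integer seed (applied once before the scan).
#' @param ladder ascending intensity ladder (default 2% steps).
#' @param threshold_mv MEP criterion amplitude, mV.
#' @param n_pulses,n_required pulses per level and required successes.
#' @return the estimated threshold intensity.
#' @export
estimate_rmt <- function(simulator, seed = 1,
                         ladder = seq(0.02, 2, by = 0.02),
                         threshold_mv = 0.05, n_pulses = 10,
                         n_required = 5) {
  stopifnot(!is.unsorted(ladder))
  found <- NA_real_
  with_seed(seed, {
    for (int in ladder) {
      meps <- vapply(seq_len(n_pulses), function(i) simulator(int), 0)
      if (sum(meps >= threshold_mv) >= n_required) {
        found <- int
        break
      }
    }
  })
  if (is.na(found))
    stop("motor threshold criterion never met on the intensity ladder")
  found
}
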