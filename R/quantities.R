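# Per-element E-field quantities: |E|, polar angle, |E_perp|, depth
# gradient, threshold look-up and the effective field E_eff.
#
# Field arrays are plain n_pulses x n_elements x 3 numeric arrays (V/m);
# quantity maps are n_pulses x n_elements matrices with a "model"
# attribute.

#' Collect per-pulse fields into a field array
#'
#' @param field_list list of `m x 3` matrices (one per pulse), V/m.
#' @param layer layer tag, e.g. `"midlayer"` or `"L5"`.
#' @return `n_pulses x m x 3` array with attribute `layer`.
#' @export
field_array <- function(field_list, layer = "midlayer") {
  n <- length(field_list)
  m <- nrow(field_list[[1]])
  arr <- array(NA_real_, c(n, m, 3))
  for (i in seq_len(n)) arr[i, , ] <- field_list[[i]]
  if (any(!is.finite(arr))) stop("fields must be finite")
  attr(arr, "layer") <- layer
  arr
}

#' E-field magnitude map (magnitude model)
#'
#' @param fields `n_pulses x m x 3` field array, V/m.
#' @return `n_pulses x m` matrix of |E|, attribute `model = "magnitude"`.
#' @export
magnitude_map <- function(fields) {
  d <- dim(fields)
  x <- matrix(sqrt(fields[, , 1]^2 + fields[, , 2]^2 + fields[, , 3]^2),
              d[1], d[2])
  attr(x, "model") <- "magnitude"
  x
}

# signed component of E along the somato-dendritic axis, n x m
axis_component <- function(fields, frames) {
  ax <- frames$axis
  d <- dim(fields)
  if (d[2] != nrow(ax))
    stop("field array and frames disagree on element count")
  comp <- function(k) matrix(fields[, , k], d[1], d[2])
  sweep(comp(1), 2, ax[, 1], `*`) + sweep(comp(2), 2, ax[, 2], `*`) +
    sweep(comp(3), 2, ax[, 3], `*`)
}

#' Polar angle between the E-field and the somato-dendritic axis
#'
#' `theta = acos(E . axis / |E|)` in degrees, in `[0, 180]`. Elements
#' with zero field have an undefined angle and propagate `NaN`;
#' consumers must mask them.
#'
#' @param fields `n_pulses x m x 3` field array.
#' @param frames [element_frames()] of the layer surface.
#' @return `n_pulses x m` matrix of angles, degrees.
#' @export
polar_angle <- function(fields, frames) {
  dot <- axis_component(fields, frames)
  mag <- magnitude_map(fields)
  ratio <- dot / mag # 0/0 -> NaN where |E| = 0
  ratio[mag == 0] <- NaN
  matrix(acos(pmin(1, pmax(-1, ratio))) * 180 / pi, nrow(mag), ncol(mag))
}

#' Absolute normal component map (cosine model)
#'
#' `x = |E . axis| = |E| |cos theta|`: the cortical column cosine model's
#' drive, assuming activation by the field component along the
#' somato-dendritic axis with either sign.
#'
#' @inheritParams polar_angle
#' @return `n_pulses x m` matrix, attribute `model = "cosine"`.
#' @export
normal_component_map <- function(fields, frames) {
  x <- abs(axis_component(fields, frames))
  attr(x, "model") <- "cosine"
  x
}

#' Relative depth gradient of the field magnitude
#'
#' `100 * (mag_deep - mag_shallow) / (mag_at_layer * separation)` in
#' %/mm: the relative change of |E| along the somato-dendritic axis per
#' unit length. Positive values mean the field grows toward the WM
#' surface. Undefined (NaN) where the layer magnitude is zero.
#'
#' @param mag_at_layer,mag_shallow,mag_deep magnitude matrices at the
#'   layer and at the two sampling points toward GM (shallow) and WM
#'   (deep).
#' @param separation geometric distance between the two sampling points,
#'   mm (scalar, per-element vector, or matrix).
#' @return matrix of gradients, %/mm.
#' @export
depth_gradient <- function(mag_at_layer, mag_shallow, mag_deep, separation) {
  if (any(separation <= 0)) stop("separation must be > 0")
  sep <- if (is.matrix(separation)) separation else
    matrix(separation, nrow(mag_at_layer), ncol(mag_at_layer), byrow = TRUE)
  g <- 100 * (mag_deep - mag_shallow) / (mag_at_layer * sep)
  g[mag_at_layer == 0] <- NaN
  g
}

#' Normalized-depth positions of the gradient sampling points
#'
#' The field is sampled at 10% of the distance from the layer toward the
#' GM surface (shallow) and toward the WM surface (deep):
#' depths `d - frac * d` and `d + frac * (1 - d)`.
#'
#' @param depth layer normalized depth in `[0, 1]`.
#' @param frac sampling offset fraction (default 0.1).
#' @return named vector `c(shallow = , deep = )` of normalized depths.
#' @export
gradient_sample_depths <- function(depth, frac = 0.1) {
  c(shallow = depth * (1 - frac), deep = depth + frac * (1 - depth))
}

#' Firing-threshold look-up table
#'
#' Grid of normalized firing thresholds `S(theta, grad)` over polar
#' angle (degrees, `[0, 180]`) and depth gradient (%/mm). `S` is the
#' threshold divided by its reference value at `theta = 0`, `grad = 0`,
#' so `S(0, 0) = 1`; `S > 1` marks less excitable orientations.
#'
#' @param theta_grid strictly increasing angles, degrees.
#' @param grad_grid strictly increasing gradients, %/mm.
#' @param S positive matrix `length(theta_grid) x length(grad_grid)`.
#' @return an object of class `threshold_lut`.
#' @export
threshold_lut <- function(theta_grid, grad_grid, S) {
  S <- as.matrix(S)
  if (is.unsorted(theta_grid, strictly = TRUE) ||
      is.unsorted(grad_grid, strictly = TRUE))
    stop("LUT grids must be strictly increasing")
  if (nrow(S) != length(theta_grid) || ncol(S) != length(grad_grid))
    stop("S has wrong dimensions")
  if (any(!is.finite(S)) || any(S <= 0)) stop("S must be positive")
  if (any(theta_grid == 0) && any(grad_grid == 0)) {
    s00 <- S[theta_grid == 0, grad_grid == 0]
    if (abs(s00 - 1) > 1e-9)
      stop("S must be normalized to 1 at (theta = 0, grad = 0)")
  }
  structure(list(theta_grid = as.numeric(theta_grid),
                 grad_grid = as.numeric(grad_grid), S = S),
            class = "threshold_lut")
}

#' @export
print.threshold_lut <- function(x, ...) {
  cat(sprintf("threshold_lut: %d theta x %d gradient nodes, S in [%.3g, %.3g]\n",
              length(x$theta_grid), length(x$grad_grid),
              min(x$S), max(x$S)))
  invisible(x)
}

#' Parametric surrogate threshold look-up table
#'
#' A smooth stand-in with the qualitative shape of the average-threshold
#' model: moderate angular tuning symmetric about 90 degrees and a weak
#' linear gradient dependence,
#' `S(theta, grad) = (1 + kappa (1 - |cos theta|)) (1 + grad_slope * grad)`,
#' renormalized so `S(0, 0) = 1`. With `kappa = 0` and `grad_slope = 0`
#' it degenerates to the identity table and the neuron model reduces to
#' the magnitude model. It is a placeholder shape, not the published
#' threshold tables.
#'
#' @param kappa angular tuning strength in `[0, 1)`; `kappa = 0.3` keeps
#'   the effective field within about 25% of |E| at 90 degrees.
#' @param grad_slope gradient sensitivity per (%/mm).
#' @param theta_grid,grad_grid grid nodes.
#' @return a [threshold_lut()].
#' @export
surrogate_lut <- function(kappa = 0.3, grad_slope = 0.005,
                          theta_grid = seq(0, 180, by = 5),
                          grad_grid = seq(-30, 30, by = 5)) {
  if (kappa < 0 || kappa >= 1) stop("kappa must be in [0, 1)")
  ang <- 1 + kappa * (1 - abs(cos(theta_grid * pi / 180)))
  grd <- 1 + grad_slope * grad_grid
  if (any(grd <= 0)) stop("grad_slope produces non-positive thresholds")
  S <- outer(ang, grd)
  S <- S / (ang[theta_grid == 0] * grd[grad_grid == 0])
  threshold_lut(theta_grid, grad_grid, S)
}

#' Bilinear look-up of normalized firing thresholds
#'
#' Bilinear interpolation of `S` at the query angles and gradients.
#' Gradients outside the table are clamped to its range (precomputed
#' tables have finite support); the clamped fraction is attached as
#' attribute `clamped_fraction`.
#'
#' @param lut a [threshold_lut()].
#' @param theta angles, degrees, in `[0, 180]` (vector or matrix).
#' @param grad gradients, %/mm (same shape as `theta`).
#' @return thresholds `S`, same shape as the inputs.
#' @export
lut_lookup <- function(lut, theta, grad) {
  stopifnot(inherits(lut, "threshold_lut"))
  dims <- dim(theta)
  th <- as.numeric(theta)
  gr <- as.numeric(grad)
  if (length(gr) != length(th)) stop("theta and grad sizes differ")
  ok <- is.finite(th) & is.finite(gr)
  if (any(th[ok] < 0 | th[ok] > 180)) stop("theta must be within [0, 180]")
  tg <- lut$theta_grid
  gg <- lut$grad_grid
  th_c <- pmin(pmax(th, tg[1]), tg[length(tg)])
  clamped <- gr[ok] < gg[1] | gr[ok] > gg[length(gg)]
  gr_c <- pmin(pmax(gr, gg[1]), gg[length(gg)])
  it <- pmin(pmax(findInterval(th_c, tg), 1), length(tg) - 1)
  ig <- pmin(pmax(findInterval(gr_c, gg), 1), length(gg) - 1)
  wt <- (th_c - tg[it]) / (tg[it + 1] - tg[it])
  wg <- (gr_c - gg[ig]) / (gg[ig + 1] - gg[ig])
  S <- lut$S
  val <- (1 - wt) * (1 - wg) * S[cbind(it, ig)] +
    wt * (1 - wg) * S[cbind(it + 1, ig)] +
    (1 - wt) * wg * S[cbind(it, ig + 1)] +
    wt * wg * S[cbind(it + 1, ig + 1)]
  val[!ok] <- NaN
  if (!is.null(dims)) dim(val) <- dims
  attr(val, "clamped_fraction") <- if (any(ok)) mean(clamped) else 0
  val
}

#' Effective E-field map (neuron model)
#'
#' `E_eff = |E| / S(theta, grad)`: the field magnitude rescaled by the
#' normalized firing threshold of the local neuronal population, so that
#' less excitable orientations (`S > 1`) are discounted. Elements with
#' zero field get `E_eff = 0`.
#'
#' @param fields `n_pulses x m x 3` field array at the layer.
#' @param frames [element_frames()] of the layer surface.
#' @param lut a [threshold_lut()].
#' @param grad depth-gradient matrix from [depth_gradient()], %/mm.
#' @return `n_pulses x m` matrix, attribute `model = "neuron"`.
#' @export
effective_field_map <- function(fields, frames, lut, grad) {
  mag <- magnitude_map(fields)
  th <- polar_angle(fields, frames)
  S <- lut_lookup(lut, th, grad)
  if (any(is.finite(S) & S <= 0)) stop("LUT integrity error: S <= 0")
  x <- mag / S
  x[mag == 0] <- 0
  x <- matrix(x, nrow(mag), ncol(mag))
  attr(x, "model") <- "neuron"
  attr(x, "clamped_fraction") <- attr(S, "clamped_fraction")
  x
}

#' Compute the quantity map of a neuronal response model
#'
#' Dispatcher over the three models: `"magnitude"` returns |E|,
#' `"cosine"` returns |E_perp|, `"neuron"` returns E_eff (which requires
#' the LUT plus the field sampled at the shallow/deep gradient points).
#'
#' @param model one of `"magnitude"`, `"cosine"`, `"neuron"`.
#' @param fields field array at the model's layer.
#' @param frames [element_frames()] of that layer.
#' @param lut [threshold_lut()] (neuron model only).
#' @param fields_shallow,fields_deep field arrays at the gradient
#'   sampling surfaces (neuron model only).
#' @param separation per-element distances between the sampling points,
#'   mm (neuron model only).
#' @return `n_pulses x m` quantity matrix with a `model` attribute.
#' @export
quantity_map <- function(model, fields, frames, lut = NULL,
                         fields_shallow = NULL, fields_deep = NULL,
                         separation = NULL) {
  model <- match.arg(model, c("magnitude", "cosine", "neuron"))
  switch(model,
    magnitude = magnitude_map(fields),
    cosine = normal_component_map(fields, frames),
    neuron = {
      if (is.null(lut) || is.null(fields_shallow) || is.null(fields_deep) ||
          is.null(separation))
        stop("neuron model requires lut, fields_shallow, fields_deep, separation")
      grad <- depth_gradient(magnitude_map(fields),
                             magnitude_map(fields_shallow),
                             magnitude_map(fields_deep), separation)
      effective_field_map(fields, frames, lut, grad)
    })
}

#' Write a threshold LUT as long-format CSV
#' @param lut a [threshold_lut()].
#' @param path output CSV (`theta_deg,grad_pct_per_mm,S`).
#' @export
write_lut <- function(lut, path) {
  df <- expand.grid(theta_deg = lut$theta_grid,
                    grad_pct_per_mm = lut$grad_grid)
  df$S <- as.vector(lut$S)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a threshold LUT from long-format CSV
#' @param path CSV with columns `theta_deg,grad_pct_per_mm,S`.
#' @return a [threshold_lut()].
#' @export
read_lut <- function(path) {
  df <- read.csv(path)
  tg <- sort(unique(df$theta_deg))
  gg <- sort(unique(df$grad_pct_per_mm))
  S <- matrix(NA_real_, length(tg), length(gg))
  S[cbind(match(df$theta_deg, tg), match(df$grad_pct_per_mm, gg))] <- df$S
  if (any(is.na(S))) stop("LUT grid is incomplete")
  threshold_lut(tg, gg, S)
}
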