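# Exhaustive coil-placement search over a scalp-centered grid, and the
# shifted control placements used in validation experiments.

#' Coil-placement search grid
#'
#' Square lattice of candidate positions in the scalp tangent plane
#' around `center` (strictly inside `radius`, then re-projected to the
#' scalp if one is given) crossed with in-plane coil orientations
#' covering `angle_range` at `angle_step`. The default 20 mm / 2 mm /
#' 360 deg / 4 deg grid has 305 positions x 90 orientations = 27450
#' configurations. Lattice membership uses strict inequality
#' (`distance < radius`); positions are generated in the tangent plane,
#' so the configuration count is exact on planar or near-planar scalps.
#'
#' @param center scalp point, mm (e.g. the projected hotspot).
#' @param radius lattice radius, mm.
#' @param spacing lattice spacing, mm.
#' @param angle_range orientation coverage, degrees.
#' @param angle_step orientation resolution, degrees (must divide
#'   `angle_range`).
#' @param e1,e2 orthonormal tangent-plane basis at `center`.
#' @param scalp optional scalp [surface_mesh()] for re-projection.
#' @return object of class `search_grid` with `positions` (P x 3),
#'   `angles` (degrees), `n_configurations`.
#' @export
make_search_grid <- function(center, radius = 20, spacing = 2,
                             angle_range = 360, angle_step = 4,
                             e1 = c(1, 0, 0), e2 = c(0, 1, 0),
                             scalp = NULL) {
  if (spacing <= 0) stop("spacing must be > 0")
  if (angle_range %% angle_step != 0)
    stop("angle_step must divide angle_range")
  span <- floor(radius / spacing)
  ij <- expand.grid(i = -span:span, j = -span:span)
  keep <- (ij$i^2 + ij$j^2) * spacing^2 < radius^2
  ij <- ij[keep, , drop = FALSE]
  if (!nrow(ij)) stop("empty search grid")
  pos <- matrix(center, nrow(ij), 3, byrow = TRUE) +
    outer(ij$i * spacing, e1) + outer(ij$j * spacing, e2)
  if (!is.null(scalp)) pos <- project_to_scalp(pos, scalp)
  angles <- seq(0, angle_range - angle_step, by = angle_step)
  structure(list(center = as.numeric(center), positions = pos,
                 angles = angles, radius = radius, spacing = spacing,
                 angle_step = angle_step,
                 n_configurations = nrow(pos) * length(angles)),
            class = "search_grid")
}

#' @export
print.search_grid <- function(x, ...) {
  cat(sprintf(
    "search_grid: %d positions x %d orientations = %d configurations (radius %g mm, spacing %g mm, step %g deg)\n",
    nrow(x$positions), length(x$angles), x$n_configurations, x$radius,
    x$spacing, x$angle_step))
  invisible(x)
}

#' Exhaustive coil-placement optimization
#'
#' Evaluates `objective(placement)` — typically the model's field
#' quantity at the R^2 hotspot — for every grid configuration and
#' returns the argmax with the full objective table. Each configuration
#' orients the coil by rotating the reference y (current) axis about the
#' reference coil normal by the grid angle. Deterministic; no
#' configuration is evaluated twice.
#'
#' @param grid a [make_search_grid()].
#' @param reference a [coil_placement()] supplying the axes and
#'   intensity (angle 0 reproduces its orientation).
#' @param objective function(placement) returning a scalar (V/m).
#' @return object of class `optimization_result`: `best` placement,
#'   `objective`, and `table` (data frame of all configurations).
#' @export
optimize_placement <- function(grid, reference, objective) {
  P <- nrow(grid$positions)
  A <- length(grid$angles)
  tab <- data.frame(pos_x = rep(grid$positions[, 1], each = A),
                    pos_y = rep(grid$positions[, 2], each = A),
                    pos_z = rep(grid$positions[, 3], each = A),
                    angle_deg = rep(grid$angles, P),
                    objective = NA_real_)
  rots <- lapply(grid$angles, function(a)
    rotation_about_axis(reference$z_axis, a))
  row <- 0L
  best_val <- -Inf
  best_pl <- NULL
  for (p in seq_len(P)) {
    for (a in seq_len(A)) {
      row <- row + 1L
      pl <- coil_placement(grid$positions[p, ],
                           as.numeric(rots[[a]] %*% reference$x_axis),
                           as.numeric(rots[[a]] %*% reference$y_axis),
                           reference$z_axis, reference$intensity)
      val <- objective(pl)
      tab$objective[row] <- val
      if (val > best_val) {
        best_val <- val
        best_pl <- pl
      }
    }
  }
  if (best_val <= 0)
    warning("all objectives are <= 0: degenerate field at the hotspot")
  structure(list(best = best_pl, objective = best_val, table = tab),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    "optimization_result: best objective %.3f V/m at (%.1f, %.1f, %.1f) mm, angle from table of %d configurations\n",
    x$objective, x$best$position[1], x$best$position[2],
    x$best$position[3], nrow(x$table)))
  invisible(x)
}

#' Shifted control coil placements
#'
#' Four placements shifted by `shift` mm along the scalp-tangent
#' anatomical axes (anterior, posterior, superior, inferior) from an
#' optimal placement, keeping its orientation, and re-projected to the
#' scalp if one is given. On the phantom, anterior is `+x` (across the
#' gyrus) and superior `+y` (along it).
#'
#' @param optimal a [coil_placement()].
#' @param shift displacement, mm (> 0).
#' @param axes named list of unit direction vectors for the four
#'   controls.
#' @param scalp optional scalp [surface_mesh()].
#' @return named list of four [coil_placement()] objects.
#' @export
control_placements <- function(optimal, shift = 10,
                               axes = list(anterior = c(1, 0, 0),
                                           posterior = c(-1, 0, 0),
                                           superior = c(0, 1, 0),
                                           inferior = c(0, -1, 0)),
                               scalp = NULL) {
  if (shift < 0) stop("shift must be >= 0")
  lapply(axes, function(u) {
    pos <- optimal$position + shift * u / vec_norm(u)
    if (!is.null(scalp)) pos <- project_to_scalp(pos, scalp)
    coil_placement(pos, optimal$x_axis, optimal$y_axis, optimal$z_axis,
                   optimal$intensity)
  })
}
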