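#' Triangulated cortical surface mesh
#'
#' Minimal container for a triangulated surface: an `n x 3` vertex matrix
#' (coordinates in mm), an `m x 3` matrix of 1-based vertex index triples,
#' and an optional per-element (per-triangle) anatomical label such as
#' `"precentral"`. Triangle indices are validated and zero-area triangles
#' rejected.
#'
#' @param vertices numeric `n x 3` matrix, mm.
#' @param triangles integer `m x 3` matrix of vertex indices (1-based).
#' @param labels optional character vector of length `m`.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, labels = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3) stop("triangles must be an m x 3 matrix")
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(triangles))
      stop("labels must have one entry per triangle")
  }
  mesh <- structure(list(vertices = vertices, triangles = triangles,
                         labels = labels),
                    class = "surface_mesh")
  areas <- triangle_areas(mesh)
  if (any(areas <= 1e-12))
    stop("mesh contains degenerate (zero-area) triangles")
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "elements")
  if (!is.null(x$labels))
    cat(" (labels:", paste(unique(x$labels), collapse = ", "), ")")
  cat("\n")
  invisible(x)
}

#' Number of elements (triangles) of a mesh
#' @param mesh a [surface_mesh()].
#' @return integer element count.
#' @export
n_elements <- function(mesh) nrow(mesh$triangles)

#' Triangle areas of a mesh
#' @param mesh a [surface_mesh()].
#' @return numeric vector of areas in mm^2.
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Element centroids of a mesh
#' @param mesh a [surface_mesh()].
#' @return `m x 3` matrix of triangle centroids, mm.
#' @export
element_centroids <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  (v[tr[, 1], , drop = FALSE] + v[tr[, 2], , drop = FALSE] +
      v[tr[, 3], , drop = FALSE]) / 3
}

#' Paired gray-/white-matter surfaces with interpolated layers
#'
#' Holds vertex-corresponding GM and WM surfaces (identical triangle
#' topology) plus named layer surfaces at normalized cortical depths,
#' where depth 0 is the GM (pial side) surface and depth 1 the WM surface.
#'
#' @param gm,wm [surface_mesh()] objects with identical `triangles`.
#' @return an object of class `layer_stack`.
#' @seealso [build_layer_surface()], [add_layer()]
#' @export
layer_stack <- function(gm, wm) {
  stopifnot(inherits(gm, "surface_mesh"), inherits(wm, "surface_mesh"))
  if (!identical(gm$triangles, wm$triangles))
    stop("gm and wm surfaces must share triangle topology")
  if (nrow(gm$vertices) != nrow(wm$vertices))
    stop("gm and wm surfaces must be vertex-corresponding")
  structure(list(gm = gm, wm = wm, layers = list()), class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat("layer_stack:", nrow(x$gm$vertices), "vertices,",
      n_elements(x$gm), "elements,", length(x$layers), "layer(s)")
  if (length(x$layers))
    cat(" [", paste(sprintf("%s=%.2f", names(x$layers),
                            vapply(x$layers, function(l) l$depth, 0)),
                    collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' Interpolate a layer surface at a normalized cortical depth
#'
#' Vertex positions are the linear blend
#' `(1 - depth) * gm + depth * wm`, so depth 0 reproduces the GM surface
#' and depth 1 the WM surface; topology (and labels) are copied from GM.
#'
#' @param stack a [layer_stack()].
#' @param depth normalized depth in `[0, 1]` (e.g. 0.4 for layer 2/3,
#'   0.65 for layer 5, 0.5 for the midlayer).
#' @return a [surface_mesh()].
#' @export
build_layer_surface <- function(stack, depth) {
  stopifnot(inherits(stack, "layer_stack"))
  if (!is.numeric(depth) || length(depth) != 1 || depth < 0 || depth > 1)
    stop("depth must be a single value in [0, 1]")
  v <- (1 - depth) * stack$gm$vertices + depth * stack$wm$vertices
  surface_mesh(v, stack$gm$triangles, stack$gm$labels)
}

#' Add a named layer to a layer stack
#' @param stack a [layer_stack()].
#' @param name layer name, e.g. `"L5"`.
#' @param depth normalized depth in `[0, 1]`.
#' @return the stack with the new layer attached.
#' @export
add_layer <- function(stack, name, depth) {
  stack$layers[[name]] <- list(depth = depth,
                               mesh = build_layer_surface(stack, depth))
  stack
}

#' Canonical layer depths
#'
#' Normalized depths of the cortical layer centers used throughout:
#' L1 0.06, L2/3 0.4, L4 0.55, L5 0.65, L6 0.85, plus the midlayer at 0.5
#' used by the magnitude and cosine models.
#'
#' @return named numeric vector of depths.
#' @export
layer_depths <- function() {
  c(L1 = 0.06, L23 = 0.4, L4 = 0.55, L5 = 0.65, L6 = 0.85, midlayer = 0.5)
}

#' Element centroids, somato-dendritic axes and areas
#'
#' For each element of `mesh` (a layer surface), returns its centroid,
#' area, and the somato-dendritic axis: the unit vector from the WM
#' element centroid to the corresponding GM element centroid, i.e.
#' pointing from white matter toward the pial surface.
#'
#' @param mesh layer [surface_mesh()] whose centroids are wanted.
#' @param gm,wm the bounding GM and WM surfaces (shared topology).
#' @return list with `centroid` (`m x 3`), `axis` (`m x 3`, unit rows),
#'   `area` (length `m`), class `element_frames`.
#' @export
element_frames <- function(mesh, gm, wm) {
  if (!identical(mesh$triangles, gm$triangles) ||
      !identical(mesh$triangles, wm$triangles))
    stop("mesh, gm and wm must share triangle topology")
  cg <- element_centroids(gm)
  cw <- element_centroids(wm)
  d <- cg - cw
  len <- row_norms(d)
  if (any(len < 1e-9))
    stop("degenerate somato-dendritic axis: coincident gm/wm centroids")
  structure(list(centroid = element_centroids(mesh),
                 axis = d / len,
                 area = triangle_areas(mesh)),
            class = "element_frames")
}

#' Edge graph of a mesh, augmented with element centroid nodes
#'
#' Vertices `1..n` are mesh vertices; vertices `n+1..n+m` are element
#' centroids, each connected to its triangle's three vertices. Edge
#' weights are Euclidean lengths (mm). Geodesic distances on this graph
#' approximate surface geodesics to within roughly one edge length.
#'
#' @param mesh a [surface_mesh()].
#' @return an [igraph::graph] with a `coords` attribute.
#' @export
mesh_graph <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  n <- nrow(v)
  m <- nrow(tr)
  cen <- element_centroids(mesh)
  # undirected mesh edges (deduplicated)
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  # centroid-to-vertex edges
  ce <- cbind(rep(n + seq_len(m), 3), as.vector(tr))
  all_e <- rbind(e, ce)
  coords <- rbind(v, cen)
  w <- row_norms(coords[all_e[, 1], , drop = FALSE] -
                   coords[all_e[, 2], , drop = FALSE])
  g <- igraph::graph_from_edgelist(all_e, directed = FALSE)
  igraph::E(g)$weight <- w
  g <- igraph::set_graph_attr(g, "n_mesh_vertices", n)
  g
}

#' Geodesic distance between two elements
#'
#' Shortest-path length over the augmented edge graph ([mesh_graph()])
#' between the two element centroids. Symmetric, non-negative, and zero
#' iff the elements coincide.
#'
#' @param mesh a [surface_mesh()].
#' @param elem_a,elem_b element ids (1-based).
#' @param graph optional precomputed [mesh_graph()] for repeated queries.
#' @return distance in mm.
#' @export
geodesic_distance <- function(mesh, elem_a, elem_b, graph = NULL) {
  d <- geodesic_distance_matrix(mesh, elem_a, elem_b, graph)
  d[1, 1]
}

#' Geodesic distances between sets of elements
#'
#' @param mesh a [surface_mesh()].
#' @param from,to element id vectors.
#' @param graph optional precomputed [mesh_graph()].
#' @return `length(from) x length(to)` matrix of distances in mm.
#' @export
geodesic_distance_matrix <- function(mesh, from, to, graph = NULL) {
  if (is.null(graph)) graph <- mesh_graph(mesh)
  n <- igraph::graph_attr(graph, "n_mesh_vertices")
  m <- n_elements(mesh)
  if (any(c(from, to) < 1L) || any(c(from, to) > m))
    stop("element id out of range")
  d <- igraph::distances(graph, v = n + from, to = n + to)
  if (any(!is.finite(d)))
    stop("elements are unreachable (disconnected mesh components)")
  dimnames(d) <- NULL
  d
}

#' Closest point on a triangulated surface
#'
#' Exact closest point on any triangle of `scalp` to each query point
#' (used to project cortical hotspots and lattice positions onto the
#' head surface).
#'
#' @param point numeric length-3 vector or `k x 3` matrix, mm.
#' @param scalp a [surface_mesh()].
#' @return matrix of projected points (`k x 3`), or a length-3 vector if
#'   a single point was given.
#' @export
project_to_scalp <- function(point, scalp) {
  single <- is.null(dim(point))
  p <- if (single) matrix(point, 1, 3) else as.matrix(point)
  if (ncol(p) != 3) stop("point must have 3 coordinates")
  v <- scalp$vertices
  tr <- scalp$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  cc <- v[tr[, 3], , drop = FALSE]
  out <- matrix(NA_real_, nrow(p), 3)
  for (i in seq_len(nrow(p))) {
    cp <- closest_point_triangles(p[i, ], a, b, cc)
    d2 <- rowSums((cp - matrix(p[i, ], nrow(cp), 3, byrow = TRUE))^2)
    out[i, ] <- cp[which.min(d2), ]
  }
  if (single) out[1, ] else out
}

# closest point on each triangle (a,b,c rows) to point p; Ericson's
# barycentric region test, vectorized over triangles
closest_point_triangles <- function(p, a, b, c) {
  ab <- b - a
  ac <- c - a
  pm <- matrix(p, nrow(a), 3, byrow = TRUE)
  ap <- pm - a
  d1 <- rowSums(ab * ap)
  d2 <- rowSums(ac * ap)
  bp <- pm - b
  d3 <- rowSums(ab * bp)
  d4 <- rowSums(ac * bp)
  cp_ <- pm - c
  d5 <- rowSums(ab * cp_)
  d6 <- rowSums(ac * cp_)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  out <- matrix(NA_real_, nrow(a), 3)
  # vertex regions
  reg <- d1 <= 0 & d2 <= 0
  out[reg, ] <- a[reg, , drop = FALSE]
  reg2 <- is.na(out[, 1]) & d3 >= 0 & d4 <= d3
  out[reg2, ] <- b[reg2, , drop = FALSE]
  reg3 <- is.na(out[, 1]) & d6 >= 0 & d5 <= d6
  out[reg3, ] <- c[reg3, , drop = FALSE]
  # edge AB
  reg4 <- is.na(out[, 1]) & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(reg4)) {
    t <- d1[reg4] / (d1[reg4] - d3[reg4])
    out[reg4, ] <- a[reg4, , drop = FALSE] + t * ab[reg4, , drop = FALSE]
  }
  # edge AC
  reg5 <- is.na(out[, 1]) & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(reg5)) {
    t <- d2[reg5] / (d2[reg5] - d6[reg5])
    out[reg5, ] <- a[reg5, , drop = FALSE] + t * ac[reg5, , drop = FALSE]
  }
  # edge BC
  reg6 <- is.na(out[, 1]) & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(reg6)) {
    t <- (d4[reg6] - d3[reg6]) /
      ((d4[reg6] - d3[reg6]) + (d5[reg6] - d6[reg6]))
    out[reg6, ] <- b[reg6, , drop = FALSE] +
      t * (c[reg6, , drop = FALSE] - b[reg6, , drop = FALSE])
  }
  # interior
  reg7 <- is.na(out[, 1])
  if (any(reg7)) {
    denom <- va[reg7] + vb[reg7] + vc[reg7]
    vv <- vb[reg7] / denom
    ww <- vc[reg7] / denom
    out[reg7, ] <- a[reg7, , drop = FALSE] + vv * ab[reg7, , drop = FALSE] +
      ww * ac[reg7, , drop = FALSE]
  }
  out
}
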