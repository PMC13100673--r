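# Shared fixtures and independent oracles. Heavy objects are built once
# per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# two flat parallel square sheets (gm above wm), unit spacing
flat_sheets <- function(n = 4, gap = 2) {
  xs <- seq(0, n - 1)
  g <- expand.grid(x = xs, y = xs)
  idx <- function(i, j) (j - 1L) * n + i
  i <- rep(seq_len(n - 1L), n - 1L)
  j <- rep(seq_len(n - 1L), each = n - 1L)
  tri <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
               cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  gm <- surface_mesh(cbind(g$x, g$y, 0), tri)
  wm <- surface_mesh(cbind(g$x, g$y, -gap), tri)
  layer_stack(gm, wm)
}

# the default study phantom plus derived geometry, shared across files
study_fixture <- function() {
  cached("study", function() {
    ph <- gyral_phantom()
    te <- phantom_true_element(ph)
    mid <- layer_inputs(ph, 0.5)
    L5 <- layer_inputs(ph, 0.65)
    ref <- reference_placement(ph)
    sc <- calibrate_primary_scale(ref, mid$frames$centroid[te, ])
    list(phantom = ph, true_element = te, mid = mid, L5 = L5,
         reference = ref, scale = sc, lut = surrogate_lut(),
         labels = ph$stack$gm$labels)
  })
}

# small phantom for the convergence-scale runs
small_fixture <- function() {
  cached("small", function() {
    ph <- gyral_phantom(n_x = 17, n_y = 17)
    te <- phantom_true_element(ph)
    mid <- layer_inputs(ph, 0.5)
    L5 <- layer_inputs(ph, 0.65)
    ref <- reference_placement(ph)
    sc <- calibrate_primary_scale(ref, mid$frames$centroid[te, ])
    list(phantom = ph, true_element = te, mid = mid, L5 = L5,
         reference = ref, scale = sc, lut = surrogate_lut(),
         labels = ph$stack$gm$labels)
  })
}

# quantity maps for all three models under a fixed placement sample
fixture_quantities <- function(fx, n_pulses, seed) {
  pl <- sample_coil_placements(fx$reference, n_pulses, seed = seed,
                               scalp = fx$phantom$scalp)
  list(placements = pl,
       magnitude = model_quantity("magnitude", pl, fx$mid,
                                  scale = fx$scale),
       cosine = model_quantity("cosine", pl, fx$mid, scale = fx$scale),
       neuron = model_quantity("neuron", pl, fx$L5, lut = fx$lut,
                               scale = fx$scale))
}

# ---- independent oracles -------------------------------------------------

# Floyd-Warshall all-pairs shortest paths on the augmented edge graph,
# built from scratch (no igraph, no package graph code)
bf_geodesic_matrix <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  n <- nrow(v)
  m <- nrow(tr)
  cen <- element_centroids(mesh)
  coords <- rbind(v, cen)
  N <- n + m
  D <- matrix(Inf, N, N)
  diag(D) <- 0
  add_edge <- function(a, b) {
    w <- sqrt(sum((coords[a, ] - coords[b, ])^2))
    D[a, b] <<- min(D[a, b], w)
    D[b, a] <<- D[a, b]
  }
  for (t in seq_len(m)) {
    add_edge(tr[t, 1], tr[t, 2])
    add_edge(tr[t, 2], tr[t, 3])
    add_edge(tr[t, 3], tr[t, 1])
    for (k in 1:3) add_edge(n + t, tr[t, k])
  }
  for (k in seq_len(N))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D[n + seq_len(m), n + seq_len(m), drop = FALSE]
}

# closest point on one triangle via plane projection + edge clamping
# (independent of the package's barycentric region implementation)
bf_closest_point <- function(p, mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  seg_closest <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    a + min(max(t, 0), 1) * ab
  }
  best <- NULL
  best_d <- Inf
  for (t in seq_len(nrow(tr))) {
    a <- v[tr[t, 1], ]; b <- v[tr[t, 2], ]; cc <- v[tr[t, 3], ]
    nrm <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
             (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
             (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    proj <- p - sum((p - a) * nrm) * nrm
    # barycentric test of the projection
    m <- cbind(b - a, cc - a)
    uv <- tryCatch(solve(crossprod(m), crossprod(m, proj - a)),
                   error = function(e) c(-1, -1))
    cand <- if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1) proj else {
      segs <- list(seg_closest(p, a, b), seg_closest(p, b, cc),
                   seg_closest(p, a, cc))
      segs[[which.min(vapply(segs, function(q) sum((p - q)^2), 0))]]
    }
    d <- sum((p - cand)^2)
    if (d < best_d) {
      best_d <- d
      best <- cand
    }
  }
  best
}

# Friedman statistic from the textbook rank-sum formula (no ties)
bf_friedman_stat <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  R <- colSums(t(apply(mat, 1, rank)))
  12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
}

# Holm step-down by explicit enumeration
bf_holm <- function(p) {
  k <- length(p)
  o <- order(p)
  adj <- pmin(p[o] * (k - seq_len(k) + 1), 1)
  adj <- cummax(adj)
  out <- numeric(k)
  out[o] <- adj
  out
}

# sample skewness
bf_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2)^1.5)
}
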