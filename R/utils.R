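# internal helpers shared across modules

# Evaluate expr under a temporary RNG state so library functions do not
# disturb the caller's random stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a stage-specific random seed from a master seed
#'
#' Stable polynomial hash of `(master, stage)` modulo 2^31 - 1, so that
#' pipeline stages can be re-run in isolation with reproducible
#' sub-streams.
#'
#' @param master integer master seed.
#' @param stage character stage tag.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  as.integer(h %% (m - 2) + 1)
}

vec_norm <- function(v) sqrt(sum(v^2))

row_norms <- function(m) sqrt(rowSums(m^2))

unit_rows <- function(m) m / row_norms(m)

# rotation matrix about a unit axis (Rodrigues), angle in degrees
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / vec_norm(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
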