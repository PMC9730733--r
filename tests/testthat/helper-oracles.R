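# Independent oracles used by the unit and acceptance tests.  These stay
# deliberately naive (explicit loops, base R arithmetic) so they do not
# share code paths with the package.

# Plain Euclidean distance between two coordinate rows.
euclid <- function(x, a, b) sqrt(sum((x[a, ] - x[b, ])^2))

# Brute-force agreement count: loops over every triplet row and evaluates
# the inequality dist(near, anchor) <= dist(anchor, far) directly.
brute_accuracy <- function(coords, trip) {
  if (is.vector(coords)) coords <- matrix(coords, ncol = 1)
  hits <- 0L
  for (row in seq_len(nrow(trip))) {
    i <- trip[row, 1]; j <- trip[row, 2]; k <- trip[row, 3]
    if (euclid(coords, j, i) <= euclid(coords, i, k)) hits <- hits + 1L
  }
  hits / nrow(trip)
}

# Brute-force hinge stress.
brute_stress <- function(coords, trip) {
  if (is.vector(coords)) coords <- matrix(coords, ncol = 1)
  s <- 0
  for (row in seq_len(nrow(trip))) {
    i <- trip[row, 1]; j <- trip[row, 2]; k <- trip[row, 3]
    h <- euclid(coords, j, i) - euclid(coords, i, k) + 1
    if (h > 0) s <- s + h^2
  }
  s
}

# Central finite differences of the stress with respect to every
# coordinate.
fd_gradient <- function(coords, trip, eps = 1e-6) {
  g <- matrix(0, nrow(coords), ncol(coords))
  for (a in seq_len(nrow(coords))) {
    for (c in seq_len(ncol(coords))) {
      up <- coords; up[a, c] <- up[a, c] + eps
      dn <- coords; dn[a, c] <- dn[a, c] - eps
      g[a, c] <- (brute_stress(up, trip) - brute_stress(dn, trip)) /
        (2 * eps)
    }
  }
  g
}

# All ordered triples (anchor, near, far) of n stimuli with near != far:
# n * (n-1) * (n-2) rows.
all_ordered_triples <- function(n) {
  out <- expand.grid(far = 1:n, near = 1:n, anchor = 1:n)
  out <- out[out$anchor != out$near & out$anchor != out$far &
               out$near != out$far, c("anchor", "near", "far")]
  as.matrix(out)
}

# Every distinct-distance triplet of a scale in its agreeing orientation
# (used to build noise-free datasets whose zero-stress solution exists by
# construction).
agreeing_triples <- function(coords) {
  if (is.vector(coords)) coords <- matrix(coords, ncol = 1)
  trip <- all_ordered_triples(nrow(coords))
  keep <- apply(trip, 1, function(t) {
    euclid(coords, t[2], t[1]) < euclid(coords, t[1], t[3])
  })
  trip[keep, , drop = FALSE]
}

# A small similarity transformation: rotation (2-D), reflection,
# translation and positive scaling applied to coordinates.
similarity_transform <- function(coords, angle = 0.7, shift = c(2, -1),
                                 scale = 3, reflect = TRUE) {
  stopifnot(ncol(coords) == 2)
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  out <- coords %*% rot
  if (reflect) out[, 1] <- -out[, 1]
  out <- scale * out
  sweep(out, 2, shift, `+`)
}
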