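# shared oracles and generators, independent of the implementation paths
# they check

# hand-rolled breadth-first-search graph distances from an adjacency list
bfs_distances <- function(adj) {
  n <- length(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (j in adj[[i]]) {
        if (is.infinite(D[s, j])) {
          D[s, j] <- D[s, i] + 1
          queue <- c(queue, j)
        }
      }
    }
  }
  D
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Evjen direct sum: Madelung potential at a rocksalt cation site with
# nearest-neighbor distance 1 (charge-neutral cube shells via fractional
# boundary weights)
evjen_madelung <- function(n = 15) {
  g <- expand.grid(i = -n:n, j = -n:n, k = -n:n)
  g <- g[!(g$i == 0 & g$j == 0 & g$k == 0), ]
  q <- (-1)^(abs(g$i) + abs(g$j) + abs(g$k))   # site at origin is +1
  w <- ifelse(abs(g$i) == n, .5, 1) * ifelse(abs(g$j) == n, .5, 1) *
    ifelse(abs(g$k) == n, .5, 1)
  sum(q * w / sqrt(g$i^2 + g$j^2 + g$k^2))
}

# rigid-rotate a structure about the origin
rotate_structure <- function(s, R) {
  p <- positions(s) %*% t(R)
  out <- new_structure(s$atoms$element, p, s$atoms$charge,
                       lattice = if (is.null(s$lattice)) NULL
                                 else s$lattice %*% t(R),
                       bonding = s$bonding)
  attr(out, "molecules") <- attr(s, "molecules")
  out
}

# translate a structure
translate_structure <- function(s, t) {
  out <- s
  p <- positions(s)
  out$atoms$x <- p[, 1] + t[1]
  out$atoms$y <- p[, 2] + t[2]
  out$atoms$z <- p[, 3] + t[3]
  out
}

# two H2 molecules along z separated along x
two_h2 <- function(gap = 10) {
  new_structure(rep("H", 4),
                rbind(c(0, 0, 0), c(0, 0, 0.74),
                      c(gap, 0, 0), c(gap, 0, 0.74)),
                bonding = bonding_scheme("center-distance", threshold = 1.0))
}
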