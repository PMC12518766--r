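# Fixtures and oracles shared across the suite. Everything is generated in
# code; heavyweight results (the full synthetic pipeline) are memoised so the
# end-to-end run happens once per session.

.fix_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fix_cache)) assign(key, force(expr), envir = .fix_cache)
  get(key, envir = .fix_cache)
}

# unit cube surface, outward-oriented (12 triangles)
cube_mesh <- function(side = 1) {
  V <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  f2 <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  F <- rbind(f2(1, 3, 4, 2), f2(5, 6, 8, 7), f2(1, 2, 6, 5),
             f2(3, 7, 8, 4), f2(1, 5, 7, 3), f2(2, 4, 8, 6))
  trimesh(V, F)
}

# random rotation matrix; max_angle (radians) bounds the rotation angle
random_rotation <- function(max_angle = pi) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, max_angle)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# brute-force parity point-in-polyhedron oracle (independent of the C++ path)
brute_inside <- function(mesh, points) {
  V <- mesh$vertices
  F <- mesh$faces
  dir <- c(0.12398471, 0.52938711, 0.83933177)
  dir <- dir / sqrt(sum(dir^2))
  vapply(seq_len(nrow(points)), function(ip) {
    o <- points[ip, ]
    cross <- 0L
    for (f in seq_len(nrow(F))) {
      a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; c_ <- V[F[f, 3], ]
      e1 <- b - a; e2 <- c_ - a
      p <- c(dir[2] * e2[3] - dir[3] * e2[2],
             dir[3] * e2[1] - dir[1] * e2[3],
             dir[1] * e2[2] - dir[2] * e2[1])
      det <- sum(e1 * p)
      if (abs(det) < 1e-13) next
      s <- o - a
      u <- sum(s * p) / det
      if (u < 0 || u > 1) next
      q <- c(s[2] * e1[3] - s[3] * e1[2],
             s[3] * e1[1] - s[1] * e1[3],
             s[1] * e1[2] - s[2] * e1[1])
      v <- sum(dir * q) / det
      if (v < 0 || u + v > 1) next
      t <- sum(e2 * q) / det
      if (t > 0) cross <- cross + 1L
    }
    cross %% 2L == 1L
  }, TRUE)
}

# radial-function quadrature volume oracle for star-shaped generators:
# V = (1/3) * sum over fine sphere faces of solid_angle * r(centroid)^3
radial_volume_oracle <- function(rfun, subdiv = 5L) {
  s <- icosphere(subdiv)
  V <- s$vertices
  F <- s$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  # solid angle of each spherical triangle (van Oosterom-Strackee)
  num <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  den <- 1 + rowSums(a * b) + rowSums(b * c_) + rowSums(c_ * a)
  omega <- 2 * atan2(num, den)
  cen <- (a + b + c_) / 3
  cen <- cen / sqrt(rowSums(cen^2))
  sum(omega * rfun(cen)^3) / 3
}

default_stack <- function() memo("stack", make_lumbar_stack(spine_params(seed = 1)))

full_pipeline <- function() memo("pipeline", {
  build_spine_model(default_stack())
})
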