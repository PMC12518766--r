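#' Unit icosphere
#'
#' Subdivided icosahedron projected to the unit sphere; the base sampling
#' domain for all synthetic structures (a radial graph over the sphere is
#' closed, manifold and self-intersection-free by construction).
#'
#' @param subdiv number of 1-to-4 subdivision rounds (>= 0).
#' @param radius sphere radius, mm.
#' @return a [trimesh].
#' @export
icosphere <- function(subdiv = 3L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  V <- V / sqrt(rowSums(V^2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(V)
    ekey <- function(a, b) (pmin(a, b) - 1) * nv + (pmax(a, b) - 1)
    keys <- c(ekey(F[, 1L], F[, 2L]), ekey(F[, 2L], F[, 3L]), ekey(F[, 3L], F[, 1L]))
    uk <- unique(keys)
    mid_id <- nv + match(keys, uk)
    a <- floor(uk / nv) + 1
    b <- uk - (a - 1) * nv + 1
    M <- (V[a, , drop = FALSE] + V[b, , drop = FALSE]) / 2
    M <- M / sqrt(rowSums(M^2))
    V <- rbind(V, M)
    nf <- nrow(F)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2L * nf + seq_len(nf)]
    F <- rbind(cbind(F[, 1L], m12, m31),
               cbind(F[, 2L], m23, m12),
               cbind(F[, 3L], m31, m23),
               cbind(m12, m23, m31))
  }
  trimesh(radius * V, F, clean = FALSE)
}

#' Synthetic lumbar fixture parameters
#'
#' Geometry of the synthetic L1--L5 stack: each vertebra is an ellipsoidal
#' body carrying a posterior arch (two pedicle-like, one spinous and two
#' transverse protrusions), each disc a rounded elliptical cylinder.
#' Superior is +z, anterior +y, left +x. Lengths in mm.
#'
#' @param n_levels number of vertebrae (discs: `n_levels - 1`).
#' @param body_radii ellipsoid semi-axes (left-right, antero-posterior,
#'   cranio-caudal).
#' @param process_length radial length of the spinous protrusion; other
#'   protrusions scale from it.
#' @param disc_height disc height along z.
#' @param disc_radii disc semi-axes (left-right, antero-posterior).
#' @param gap clearance between a vertebral body and the adjacent disc.
#' @param seed integer seed driving the smooth surface noise.
#' @param noise_amplitude peak radial surface perturbation.
#' @param mesh_subdiv icosphere subdivision per structure (resolution knob).
#' @export
spine_params <- function(n_levels = 5L, body_radii = c(20, 15, 12),
                         process_length = 25, disc_height = 10,
                         disc_radii = c(18, 13), gap = 0.5, seed = 1L,
                         noise_amplitude = 0.2, mesh_subdiv = 4L) {
  n_levels <- as.integer(n_levels)
  stopifnot(n_levels >= 2L, length(body_radii) == 3L, length(disc_radii) == 2L)
  if (any(c(body_radii, process_length, disc_height, disc_radii) <= 0))
    stop("all lengths must be positive")
  if (gap <= 0 || gap >= disc_height) stop("need 0 < gap < disc_height")
  if (noise_amplitude < 0 || noise_amplitude >= 0.1 * min(body_radii, disc_radii))
    stop("noise_amplitude must be < 10% of the smallest semi-axis")
  structure(list(n_levels = n_levels, body_radii = as.numeric(body_radii),
                 process_length = process_length, disc_height = disc_height,
                 disc_radii = as.numeric(disc_radii), gap = gap,
                 seed = as.integer(seed), noise_amplitude = noise_amplitude,
                 mesh_subdiv = as.integer(mesh_subdiv)),
            class = "spine_params")
}

# vertical spacing between adjacent vertebra body centers
.stack_spacing <- function(params)
  2 * params$body_radii[3L] + params$disc_height + 2 * params$gap

#' Stacking height (z of the body center) of a vertebra level
#' @param params a [spine_params].
#' @param level 1 (L1, most superior) .. n_levels.
#' @export
level_height <- function(params, level)
  (params$n_levels - level) * .stack_spacing(params)

# smooth seeded radial perturbation: low-order trigonometric field over the
# sphere, damped at the z poles so endplate gaps stay intact
.smooth_noise <- function(U, amplitude, seed) {
  if (amplitude <= 0) return(numeric(nrow(U)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  co <- stats::runif(12L, -1, 1)
  x <- U[, 1L]; y <- U[, 2L]; z <- U[, 3L]
  f <- co[1L] * x + co[2L] * y + co[3L] * z +
    co[4L] * x * y + co[5L] * y * z + co[6L] * x * z +
    co[7L] * (x^2 - y^2) + co[8L] * (3 * z^2 - 1) / 2 +
    co[9L] * sin(3 * atan2(y, x)) * (1 - z^2) +
    co[10L] * cos(2 * atan2(y, x)) * (1 - z^2) +
    co[11L] * x * y * z + co[12L] * sin(2 * pi * z)
  f <- f * (1 - z^2)  # quiet at the poles
  if (max(abs(f)) < 1e-12) return(numeric(nrow(U)))
  amplitude * f / max(abs(f))
}

# angular Gaussian bump field: amplitude * exp(-(angle(u, dir)/sigma)^2)
.bump <- function(U, dir, amplitude, sigma) {
  dir <- dir / sqrt(sum(dir^2))
  ang <- acos(pmin(1, pmax(-1, U %*% dir)))
  amplitude * exp(-(ang / sigma)^2)
}

# radial profile of the vertebra in its local frame (unit directions U)
.vertebra_radius <- function(U, params) {
  a <- params$body_radii
  r <- 1 / sqrt((U[, 1L] / a[1L])^2 + (U[, 2L] / a[2L])^2 + (U[, 3L] / a[3L])^2)
  L <- params$process_length
  r <- r + .bump(U, c(0, -1, 0), L, 0.22)                 # spinous
  r <- r + .bump(U, c(1, -0.35, 0), 0.55 * L, 0.18)       # transverse left
  r <- r + .bump(U, c(-1, -0.35, 0), 0.55 * L, 0.18)      # transverse right
  r <- r + .bump(U, c(0.45, -0.9, 0.1), 0.35 * L, 0.25)   # pedicle left
  r <- r + .bump(U, c(-0.45, -0.9, 0.1), 0.35 * L, 0.25)  # pedicle right
  drop(r)
}

#' Synthetic vertebra mesh
#'
#' Closed manifold vertebra-like surface: an ellipsoidal body with a
#' posterior arch, built as a radial graph over an icosphere (hence
#' star-shaped from its body center), with seeded smooth noise. Centered at
#' the level's stacking height. Deterministic for fixed (params, level).
#'
#' @param params a [spine_params].
#' @param level vertebra level, 1 (L1) .. n_levels (L5 most inferior).
#' @return a [trimesh].
#' @export
make_vertebra <- function(params, level) {
  stopifnot(inherits(params, "spine_params"))
  level <- as.integer(level)
  if (is.na(level) || level < 1L || level > params$n_levels)
    stop("level must be in 1..", params$n_levels)
  base <- icosphere(params$mesh_subdiv)
  U <- base$vertices
  r <- .vertebra_radius(U, params)
  r <- r + .smooth_noise(U, params$noise_amplitude,
                         params$seed + 7919L * level)
  V <- U * r
  V[, 3L] <- V[, 3L] + level_height(params, level)
  trimesh(V, base$faces, clean = FALSE)
}

# superellipsoid radial profile: rounded elliptical cylinder
.disc_radius <- function(U, params, p = 6) {
  a <- params$disc_radii[1L]
  b <- params$disc_radii[2L]
  cc <- params$disc_height / 2
  q <- ((U[, 1L] / a)^2 + (U[, 2L] / b)^2)^(p / 2) + abs(U[, 3L] / cc)^p
  drop(q^(-1 / p))
}

#' Synthetic intervertebral disc mesh
#'
#' Closed rounded elliptical cylinder placed midway between vertebra levels
#' `level` and `level + 1`; its two largest-variance principal directions
#' span the transverse plane.
#'
#' @param params a [spine_params].
#' @param level disc level, 1 .. n_levels - 1 (D1 sits between L1 and L2).
#' @return a [trimesh].
#' @export
make_disc <- function(params, level) {
  stopifnot(inherits(params, "spine_params"))
  level <- as.integer(level)
  if (is.na(level) || level < 1L || level > params$n_levels - 1L)
    stop("disc level must be in 1..", params$n_levels - 1L)
  base <- icosphere(params$mesh_subdiv)
  U <- base$vertices
  r <- .disc_radius(U, params)
  r <- r + .smooth_noise(U, 0.5 * params$noise_amplitude,
                         params$seed + 7919L * level + 977L)
  V <- U * r
  zc <- (level_height(params, level) + level_height(params, level + 1L)) / 2
  V[, 3L] <- V[, 3L] + zc
  trimesh(V, base$faces, clean = FALSE)
}

#' Synthetic L1--L5 lumbar stack
#'
#' Labeled map of `n_levels` vertebrae (`L1` superior .. `L5` inferior) and
#' `n_levels - 1` discs (`D1` between L1/L2, ...), mutually non-intersecting,
#' stacked along +z.
#'
#' @param params a [spine_params].
#' @return named list of [trimesh] objects with attribute `params`.
#' @export
make_lumbar_stack <- function(params = spine_params()) {
  stopifnot(inherits(params, "spine_params"))
  out <- list()
  for (k in seq_len(params$n_levels))
    out[[paste0("L", k)]] <- make_vertebra(params, k)
  for (k in seq_len(params$n_levels - 1L))
    out[[paste0("D", k)]] <- make_disc(params, k)
  attr(out, "params") <- params
  out
}
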