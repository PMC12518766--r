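#' Spherical coordinate triple for an attachment plane normal
#'
#' `phi` is the polar angle from the superior (+z) axis, `theta` the
#' azimuth in the transverse plane, both in degrees; `r` is a signed
#' magnitude in mm. A negative `r` reverses the selected side of the plane.
#'
#' @param phi,theta angles in degrees.
#' @param r signed magnitude, mm.
#' @export
spherical_coordinate <- function(phi, theta, r) {
  stopifnot(is.finite(phi), is.finite(theta), is.finite(r))
  structure(list(phi = phi, theta = theta, r = r), class = "spherical_coordinate")
}

#' Spherical-to-Cartesian conversion of a plane normal
#'
#' `N = r (sin phi cos theta, sin phi sin theta, cos phi)`, angles in
#' degrees.
#'
#' @param c a [spherical_coordinate].
#' @return length-3 numeric vector.
#' @export
spherical_to_cartesian <- function(c) {
  stopifnot(inherits(c, "spherical_coordinate"))
  p <- c$phi * pi / 180
  t <- c$theta * pi / 180
  c$r * c(sin(p) * cos(t), sin(p) * sin(t), cos(p))
}

#' Attachment plane (origin + normal)
#' @param origin plane origin (the vertebral center), length-3.
#' @param normal plane normal, length-3, non-zero.
#' @export
attachment_plane <- function(origin, normal) {
  normal <- as.numeric(normal)
  if (sqrt(sum(normal^2)) <= 0) stop("zero plane normal")
  structure(list(origin = as.numeric(origin), normal = normal),
            class = "attachment_plane")
}

#' Half-space vertex selection
#'
#' Exactly the mesh vertices with `N . (P - O) > 0` (strict). An empty
#' selection is allowed but warned about.
#'
#' @param mesh a [trimesh].
#' @param plane an [attachment_plane].
#' @return integer vector of vertex indices.
#' @export
select_attachment_vertices <- function(mesh, plane) {
  stopifnot(inherits(plane, "attachment_plane"))
  s <- drop(sweep(mesh$vertices, 2L, plane$origin) %*% plane$normal)
  out <- which(s > 0)
  if (length(out) == 0L) warning("empty attachment selection")
  out
}

#' Attachment region from a spherical-coordinate plane
#'
#' Builds the plane through `center` with normal from
#' [spherical_to_cartesian()] and applies [select_attachment_vertices()];
#' a negative `r` selects the complementary side.
#'
#' @param mesh a [trimesh].
#' @param center the vertebral center (plane origin).
#' @param coord a [spherical_coordinate].
#' @return integer vector of vertex indices.
#' @export
attachment_region <- function(mesh, center, coord) {
  select_attachment_vertices(mesh, attachment_plane(center,
                                                    spherical_to_cartesian(coord)))
}

#' Posterior-longitudinal attachment: closest-n posterior vertices
#'
#' The `n` vertices nearest the vertebral center, restricted to candidates
#' posterior to it (y < center y in the anterior = +y frame). Ties broken
#' by lower vertex index; if fewer than `n` candidates exist, all are
#' returned with a warning.
#'
#' @param mesh a [trimesh].
#' @param center vertebral center.
#' @param n number of points (default 20).
#' @export
pll_attachment <- function(mesh, center, n = 20L) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  cand <- which(mesh$vertices[, 2L] < center[2L])
  if (length(cand) == 0L) stop("no posterior vertices")
  if (length(cand) < n) {
    warning("fewer than n posterior candidates; returning all ", length(cand))
    return(cand)
  }
  d <- sqrt(rowSums(sweep(mesh$vertices[cand, , drop = FALSE], 2L, center)^2))
  cand[order(d, cand)[seq_len(n)]]
}

#' Midpoint anchor between adjacent vertebral centers (ligamentum flavum)
#'
#' @param center_upper,center_lower distinct length-3 points.
#' @return their arithmetic midpoint.
#' @export
lf_midpoints <- function(center_upper, center_lower) {
  if (sqrt(sum((center_upper - center_lower)^2)) < 1e-12)
    stop("coincident vertebral centers")
  (as.numeric(center_upper) + as.numeric(center_lower)) / 2
}

# nearest posterior vertex of a mesh to a point
.nearest_posterior_vertex <- function(mesh, point, center) {
  cand <- which(mesh$vertices[, 2L] < center[2L])
  if (length(cand) == 0L) cand <- seq_len(nrow(mesh$vertices))
  d <- rowSums(sweep(mesh$vertices[cand, , drop = FALSE], 2L, point)^2)
  cand[which.min(d)]
}

#' Build spring elements between two attachment regions
#'
#' `n_springs` anchor vertices are spread over the upper region by
#' farthest-point sampling (seeded at the vertex nearest the region
#' centroid); each is paired with its nearest vertex in the lower region.
#' Rest lengths are the current Euclidean distances.
#'
#' @param mesh_upper,mesh_lower the two meshes carrying the regions.
#' @param region_upper,region_lower vertex-index sets on their meshes.
#' @param n_springs number of springs (default 10).
#' @param name ligament name carried through to the result.
#' @param parts length-2 character: part identifiers for bookkeeping.
#' @return object of class `spring_set`.
#' @export
build_ligament_springs <- function(mesh_upper, region_upper, mesh_lower,
                                   region_lower, n_springs = 10L,
                                   name = "ligament",
                                   parts = c("upper", "lower")) {
  n_springs <- as.integer(n_springs)
  if (length(region_upper) == 0L || length(region_lower) == 0L)
    stop("empty attachment region for ligament '", name, "'")
  P <- mesh_upper$vertices[region_upper, , drop = FALSE]
  Q <- mesh_lower$vertices[region_lower, , drop = FALSE]
  # farthest-point sampling on the upper region
  cen <- colMeans(P)
  seed <- which.min(rowSums(sweep(P, 2L, cen)^2))
  picked <- seed
  if (n_springs > 1L) {
    d2 <- rowSums(sweep(P, 2L, P[seed, ])^2)
    for (k in 2:min(n_springs, nrow(P))) {
      nxt <- which.max(d2)
      picked <- c(picked, nxt)
      d2 <- pmin(d2, rowSums(sweep(P, 2L, P[nxt, ])^2))
    }
    while (length(picked) < n_springs)  # fewer region vertices than springs
      picked <- c(picked, picked[seq_len(n_springs - length(picked))])
  }
  up_idx <- region_upper[picked]
  lo_idx <- integer(length(picked))
  for (i in seq_along(picked)) {
    d2q <- rowSums(sweep(Q, 2L, mesh_upper$vertices[up_idx[i], ])^2)
    lo_idx[i] <- region_lower[which.min(d2q)]
  }
  rest <- sqrt(rowSums((mesh_upper$vertices[up_idx, , drop = FALSE] -
                          mesh_lower$vertices[lo_idx, , drop = FALSE])^2))
  if (any(rest <= 0)) stop("zero-length spring in ligament '", name, "'")
  structure(list(name = name,
                 endpoints = data.frame(part_upper = parts[1L], node_upper = up_idx,
                                        part_lower = parts[2L], node_lower = lo_idx,
                                        rest_length = rest,
                                        stringsAsFactors = FALSE)),
            class = "spring_set")
}

#' @export
print.spring_set <- function(x, ...) {
  cat(sprintf("spring_set '%s': %d springs, rest length %.2f-%.2f mm\n",
              x$name, nrow(x$endpoints), min(x$endpoints$rest_length),
              max(x$endpoints$rest_length)))
  invisible(x)
}

#' Published ligament attachment table
#'
#' The default attachment parameters for the lumbar spine: nine plane-mode
#' rows given as spherical coordinates (phi, theta, r; degrees and mm)
#' about the vertebral center, the posterior longitudinal ligament as the
#' closest-N posterior points, and the ligamentum flavum anchored at
#' midpoints between adjacent vertebral centers. Every ligament is realized
#' as 10 spring elements.
#'
#' @param n_springs springs per ligament instance.
#' @param pll_closest_n N for the posterior longitudinal ligament.
#' @return list of `ligament_spec` entries (11 rows).
#' @export
default_ligament_table <- function(n_springs = 10L, pll_closest_n = 20L) {
  plane <- function(name, phi, theta, r)
    structure(list(name = name, mode = "plane",
                   coords = spherical_coordinate(phi, theta, r),
                   n_springs = as.integer(n_springs)), class = "ligament_spec")
  out <- list(
    plane("ALL_lower", 29.063, -85, 18),
    plane("ALL_upper", 30, -85, -8),
    plane("ITL_left", 35, 30, -1),
    plane("ITL_right", 35, 156, -1),
    plane("CL_lower_left", 25, 128.63, 16),
    plane("CL_lower_right", 18, 61, 21),
    plane("CL_upper_left", -4, 30, -28),
    plane("CL_upper_right", -4, 140, -27),
    plane("SSL_ISL", 25, 90.7, -30),
    structure(list(name = "PLL", mode = "closest_n",
                   closest_n = as.integer(pll_closest_n),
                   n_springs = as.integer(n_springs)), class = "ligament_spec"),
    structure(list(name = "LF", mode = "midpoint",
                   n_springs = as.integer(n_springs)), class = "ligament_spec"))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Ligament springs for one motion segment
#'
#' Applies the attachment table to an adjacent vertebra pair. Pairing rule:
#' `lower`-labeled rows select on the upper vertebra and pair with the
#' matching `upper`-labeled rows on the lower vertebra (ALL, CL);
#' single-row ligaments (ITL, SSL/ISL) apply the same plane to both
#' vertebrae; PLL pairs the closest-N posterior sets; LF anchors both
#' vertebrae to their nearest posterior vertices around the center
#' midpoint.
#'
#' @param mesh_upper,mesh_lower vertebra [trimesh]es (upper = more cranial).
#' @param parts length-2 character part ids for the two vertebrae.
#' @param table ligament table from [default_ligament_table()].
#' @param lf_closest_n region size used around the LF midpoint anchor.
#' @return named list of `spring_set`s (8 ligament instances).
#' @export
segment_ligaments <- function(mesh_upper, mesh_lower,
                              parts = c("upper", "lower"),
                              table = default_ligament_table(),
                              lf_closest_n = 20L) {
  cu <- centroid(mesh_upper)
  cl <- centroid(mesh_lower)
  reg <- function(mesh, center, spec) attachment_region(mesh, center, spec$coords)
  springs <- list()
  mk <- function(name, ru, rl, n)
    build_ligament_springs(mesh_upper, ru, mesh_lower, rl, n, name, parts)
  tb <- table
  springs$ALL <- mk("ALL", reg(mesh_upper, cu, tb$ALL_lower),
                    reg(mesh_lower, cl, tb$ALL_upper), tb$ALL_lower$n_springs)
  springs$ITL_left <- mk("ITL_left", reg(mesh_upper, cu, tb$ITL_left),
                         reg(mesh_lower, cl, tb$ITL_left), tb$ITL_left$n_springs)
  springs$ITL_right <- mk("ITL_right", reg(mesh_upper, cu, tb$ITL_right),
                          reg(mesh_lower, cl, tb$ITL_right), tb$ITL_right$n_springs)
  springs$CL_left <- mk("CL_left", reg(mesh_upper, cu, tb$CL_lower_left),
                        reg(mesh_lower, cl, tb$CL_upper_left),
                        tb$CL_lower_left$n_springs)
  springs$CL_right <- mk("CL_right", reg(mesh_upper, cu, tb$CL_lower_right),
                         reg(mesh_lower, cl, tb$CL_upper_right),
                         tb$CL_lower_right$n_springs)
  springs$SSL_ISL <- mk("SSL_ISL", reg(mesh_upper, cu, tb$SSL_ISL),
                        reg(mesh_lower, cl, tb$SSL_ISL), tb$SSL_ISL$n_springs)
  springs$PLL <- mk("PLL", pll_attachment(mesh_upper, cu, tb$PLL$closest_n),
                    pll_attachment(mesh_lower, cl, tb$PLL$closest_n),
                    tb$PLL$n_springs)
  mid <- lf_midpoints(cu, cl)
  lf_region <- function(mesh, center) {
    cand <- which(mesh$vertices[, 2L] < center[2L])
    d <- rowSums(sweep(mesh$vertices[cand, , drop = FALSE], 2L, mid)^2)
    cand[order(d)[seq_len(min(lf_closest_n, length(cand)))]]
  }
  springs$LF <- mk("LF", lf_region(mesh_upper, cu), lf_region(mesh_lower, cl),
                   tb$LF$n_springs)
  springs
}
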