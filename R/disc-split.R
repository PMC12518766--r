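#' Principal-component frame of a point cloud
#'
#' Mean point plus orthonormal principal axes ordered by descending
#' variance (1/(n-1) covariance normalization). Eigenvector signs are fixed
#' deterministically: the least-variance axis `u3` points toward global +z
#' (superior), `u1` toward +y (anterior), and `u2 = u3 x u1` completes a
#' right-handed triad. Ties in the eigenvalues are broken by assigning the
#' tied eigenvector most aligned with global z to `u3`.
#'
#' @param points `n x 3` matrix (n >= 2; rank deficiency is allowed and
#'   reported as zero variance).
#' @return object of class `pca_frame`: `mean`, `axes` (columns u1,u2,u3),
#'   `variances`.
#' @export
pca_frame <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points for a PCA frame")
  m <- colMeans(points)
  X <- sweep(points, 2L, m)
  S <- crossprod(X) / (nrow(points) - 1L)
  e <- eigen(S, symmetric = TRUE)
  val <- pmax(e$values, 0)
  vec <- e$vectors  # columns, descending eigenvalue
  # Ties: within a tied eigenspace every direction is an eigenvector, so the
  # frame is pinned to the anatomical axes there — u3 becomes the projection
  # of global +z onto the eigenspace tied with the smallest eigenvalue, and
  # u1 the projection of +y when the two largest eigenvalues tie.
  tol <- max(val[1L], 1) * 1e-9
  tied3 <- which(abs(val - val[3L]) <= tol)
  u3 <- vec[, 3L]
  if (length(tied3) > 1L) {
    B <- vec[, tied3, drop = FALSE]
    for (ref in list(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))) {
      pz <- B %*% crossprod(B, ref)
      if (sqrt(sum(pz^2)) > 1e-9) {
        u3 <- drop(pz) / sqrt(sum(pz^2))
        break
      }
    }
  }
  if (sum(u3 * c(0, 0, 1)) < 0 ||
      (abs(sum(u3 * c(0, 0, 1))) < 1e-12 && sum(u3 * c(0, 1, 0)) < 0))
    u3 <- -u3
  u1 <- vec[, 1L]
  if (abs(val[1L] - val[2L]) <= tol) {
    for (ref in list(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))) {
      p1 <- ref - sum(ref * u3) * u3
      if (sqrt(sum(p1^2)) > 1e-9) {
        u1 <- p1 / sqrt(sum(p1^2))
        break
      }
    }
  } else {
    u1 <- u1 - sum(u1 * u3) * u3  # exact orthogonality after a u3 tie-fix
    u1 <- u1 / sqrt(sum(u1^2))
  }
  if (sum(u1 * c(0, 1, 0)) < 0 ||
      (abs(sum(u1 * c(0, 1, 0))) < 1e-12 && sum(u1 * c(1, 0, 0)) < 0))
    u1 <- -u1
  u2 <- c(u3[2L] * u1[3L] - u3[3L] * u1[2L],
          u3[3L] * u1[1L] - u3[1L] * u1[3L],
          u3[1L] * u1[2L] - u3[2L] * u1[1L])
  axes <- cbind(u1, u2, u3, deparse.level = 0)
  # snap numerically-zero components so axis-aligned clouds get exact axes
  axes[abs(axes) < 1e-12] <- 0
  axes <- sweep(axes, 2L, sqrt(colSums(axes^2)), "/")
  structure(list(mean = m, axes = axes, variances = val), class = "pca_frame")
}

#' @export
print.pca_frame <- function(x, ...) {
  cat("pca_frame: variances", paste(signif(x$variances, 4), collapse = ", "), "\n")
  invisible(x)
}

# project points into the frame's (u1,u2[,u3]) coordinates
.to_frame <- function(frame, points, k = 2L)
  sweep(as.matrix(points), 2L, frame$mean) %*% frame$axes[, seq_len(k), drop = FALSE]

.from_frame <- function(frame, uv, w = 0)
  sweep(cbind(uv, w) %*% t(frame$axes), 2L, frame$mean, "+")

#' Closed boundary curve (class `boundary_curve`)
#'
#' Ordered closed polyline (first point not repeated) lying in a
#' [pca_frame]'s (u1,u2) plane.
#'
#' @param points `n x 3` matrix, n >= 3.
#' @param frame the [pca_frame] the curve lies in.
#' @export
boundary_curve <- function(points, frame) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("a boundary curve needs at least 3 points")
  structure(list(points = points, frame = frame), class = "boundary_curve")
}

# perimeter of a closed polyline
.curve_perimeter <- function(P) {
  Q <- P[c(2:nrow(P), 1L), , drop = FALSE]
  sum(sqrt(rowSums((Q - P)^2)))
}

# equal-arc-length resampling of an open polyline to n points (endpoints kept)
.resample_open <- function(P, n) {
  seg <- sqrt(rowSums(diff(P)^2))
  cum <- c(0, cumsum(seg))
  tot <- cum[length(cum)]
  t_new <- tot * (seq_len(n) - 1L) / (n - 1L)
  idx <- pmin(findInterval(t_new, cum, rightmost.closed = TRUE), nrow(P) - 1L)
  w <- (t_new - cum[idx]) / pmax(seg[idx], 1e-300)
  P[idx, , drop = FALSE] + (P[idx + 1L, , drop = FALSE] - P[idx, , drop = FALSE]) * w
}

# equal-arc-length resampling of a closed polyline to n points
.resample_closed <- function(P, n) {
  Q <- rbind(P, P[1L, ])
  seg <- sqrt(rowSums(diff(Q)^2))
  cum <- c(0, cumsum(seg))
  tot <- cum[length(cum)]
  t_new <- tot * (seq_len(n) - 1L) / n
  idx <- findInterval(t_new, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(Q)] <- nrow(Q) - 1L
  w <- (t_new - cum[idx]) / pmax(seg[idx], 1e-300)
  P0 <- Q[idx, , drop = FALSE]
  P1 <- Q[idx + 1L, , drop = FALSE]
  P0 + (P1 - P0) * w
}

#' Outer boundary of a disc projected to its PCA plane
#'
#' Disc vertices are projected to the (u1,u2) plane through the frame mean;
#' the outer boundary is the 2-D concave hull (alpha shape with alpha set
#' to twice the median mesh edge length, falling back to the convex hull),
#' resampled to `n_samples` points at equal arc length and ordered
#' counter-clockwise in (u1,u2).
#'
#' @param disc disc [trimesh].
#' @param frame [pca_frame] of the disc's own vertices.
#' @param n_samples number of curve points (>= 8).
#' @return a [boundary_curve].
#' @export
disc_boundary_curve <- function(disc, frame, n_samples = 64L) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 8L) stop("n_samples must be >= 8")
  if (frame$variances[2L] <= 1e-12)
    stop("degenerate projection: second principal variance is zero")
  uv <- .to_frame(frame, disc$vertices)
  alpha <- 2 * stats::median(edge_lengths(disc))
  loop2 <- .alpha_boundary(uv, alpha)
  res <- .resample_closed(loop2, n_samples)
  boundary_curve(.from_frame(frame, res), frame)
}

# 2-D outer boundary via alpha shape (convex-hull fallback); returns an
# ordered CCW closed polyline (k x 2)
.alpha_boundary <- function(uv, alpha) {
  hull_fallback <- function() {
    h <- grDevices::chull(uv[, 1L], uv[, 2L])
    uv[rev(h), , drop = FALSE]  # chull is clockwise; reverse to CCW
  }
  # mirror-symmetric surfaces project coincident points; collapse them
  # before triangulating (duplicates degrade the incremental Delaunay)
  key <- sprintf("%.0f %.0f", round(uv[, 1L] * 1e7), round(uv[, 2L] * 1e7))
  uv <- uv[!duplicated(key), , drop = FALSE]
  tri <- tryCatch(cpp_delaunay2d(uv[, 1L], uv[, 2L]), error = function(e) NULL)
  if (is.null(tri) || nrow(tri) == 0L) return(hull_fallback())
  a <- uv[tri[, 1L], , drop = FALSE]
  b <- uv[tri[, 2L], , drop = FALSE]
  cc <- uv[tri[, 3L], , drop = FALSE]
  # circumradius = abc / (4 * area)
  la <- sqrt(rowSums((b - cc)^2))
  lb <- sqrt(rowSums((a - cc)^2))
  lc <- sqrt(rowSums((a - b)^2))
  ar2 <- abs((b[, 1L] - a[, 1L]) * (cc[, 2L] - a[, 2L]) -
               (b[, 2L] - a[, 2L]) * (cc[, 1L] - a[, 1L]))
  R <- la * lb * lc / pmax(2 * ar2, 1e-300)
  keep <- tri[R < alpha, , drop = FALSE]
  if (nrow(keep) == 0L) return(hull_fallback())
  # boundary loops of the kept triangle set, traced with the same face-fan
  # walker used for surface patches (robust at pinch vertices); the outer
  # loop is the one with the largest CCW area
  loops <- tryCatch(
    .patch_boundary_loops(list(faces = keep), seq_len(nrow(keep))),
    error = function(e) list())
  if (length(loops) == 0L) return(hull_fallback())
  areas <- vapply(loops, function(l) {
    P <- uv[l, , drop = FALSE]
    Q <- P[c(2:nrow(P), 1L), , drop = FALSE]
    0.5 * sum(P[, 1L] * Q[, 2L] - Q[, 1L] * P[, 2L])
  }, 0)
  loop <- loops[[which.max(areas)]]  # outer loop: largest signed (CCW) area
  if (max(areas) <= 0) return(hull_fallback())
  uv[loop, , drop = FALSE]
}

#' Scale a boundary curve about its centroid
#'
#' Similarity map `p -> c + s (p - c)` with `c` the curve centroid
#' (`C_nucleus = s * C_disc`).
#'
#' @param curve a [boundary_curve].
#' @param s scale factor in (0, 1].
#' @export
scale_curve <- function(curve, s) {
  if (!is.numeric(s) || length(s) != 1L || s <= 0 || s > 1)
    stop("scale factor must be in (0, 1]")
  cen <- colMeans(curve$points)
  out <- curve
  out$points <- sweep(sweep(curve$points, 2L, cen) * s, 2L, cen, "+")
  out
}

#' Extrude-and-clip nucleus solid from a scaled boundary curve
#'
#' The scaled curve is swept along the frame's u3 axis across the disc and
#' clipped to the disc interior: for every in-plane sample point the top
#' and bottom z are found by casting a u3 ray against the disc surface, so
#' the caps conform to the disc. Sampling density (rings, angular stations
#' and vertical levels) follows `point_spacing`.
#'
#' @param curve scaled [boundary_curve] (from [scale_curve()]).
#' @param disc closed disc [trimesh].
#' @param point_spacing target sample spacing, mm.
#' @return closed [trimesh] of the clipped cylindrical nucleus.
#' @export
build_nucleus_solid <- function(curve, disc, point_spacing = 1) {
  if (point_spacing <= 0) stop("point_spacing must be > 0")
  frame <- curve$frame
  uv <- .to_frame(frame, curve$points)
  c2 <- colMeans(uv)
  per <- .curve_perimeter(uv)
  M <- max(16L, as.integer(round(per / point_spacing)))
  ring_uv <- .resample_closed(uv, M)
  mean_r <- mean(sqrt(rowSums(sweep(ring_uv, 2L, c2)^2)))
  K <- max(2L, as.integer(ceiling(mean_r / point_spacing)))
  u3 <- frame$axes[, 3L]
  # planar grid: ring j = center + (j/K) * (curve - center), j = 0 (center) .. K
  grids <- lapply(seq_len(K), function(j)
    sweep(sweep(ring_uv, 2L, c2) * (j / K), 2L, c2, "+"))
  all_uv <- rbind(matrix(c2, 1L, 2L), do.call(rbind, grids))
  P3 <- .from_frame(frame, all_uv)
  zr <- .ray_span(disc, P3, u3, shrink_to = .from_frame(frame, matrix(c2, 1L, 2L)))
  npt <- nrow(all_uv)
  ztop <- zr[, 2L]
  zbot <- zr[, 1L]
  hmax <- max(ztop - zbot)
  Kz <- max(2L, as.integer(ceiling(hmax / point_spacing)))
  # vertex table: top sheet, bottom sheet, wall levels on the outer ring
  Vtop <- P3 + outer(ztop, u3)
  Vbot <- P3 + outer(zbot, u3)
  id_top <- seq_len(npt)
  id_bot <- npt + seq_len(npt)
  V <- rbind(Vtop, Vbot)
  outer_ids <- 1L + (K - 1L) * M + seq_len(M)  # indices of ring K in sheets
  wall_levels <- list()
  if (Kz > 1L) {
    for (l in seq_len(Kz - 1L)) {
      w <- l / Kz
      Vl <- Vbot[outer_ids, , drop = FALSE] * (1 - w) + Vtop[outer_ids, , drop = FALSE] * w
      wall_levels[[l]] <- nrow(V) + seq_len(M)
      V <- rbind(V, Vl)
    }
  }
  faces <- list()
  nxt_i <- c(2:M, 1L)
  # caps: center fans + ring strips (CCW from +u3 on top; reversed below)
  ring_ids <- function(j) 1L + (j - 1L) * M + seq_len(M)
  fan_top <- cbind(id_top[1L], id_top[ring_ids(1L)], id_top[ring_ids(1L)][nxt_i])
  fan_bot <- cbind(id_bot[1L], id_bot[ring_ids(1L)][nxt_i], id_bot[ring_ids(1L)])
  faces <- c(faces, list(fan_top, fan_bot))
  if (K > 1L) for (j in seq_len(K - 1L)) {
    a <- id_top[ring_ids(j)]
    b <- id_top[ring_ids(j + 1L)]
    faces[[length(faces) + 1L]] <- rbind(cbind(a, b, b[nxt_i]),
                                         cbind(a, b[nxt_i], a[nxt_i]))
    a <- id_bot[ring_ids(j)]
    b <- id_bot[ring_ids(j + 1L)]
    faces[[length(faces) + 1L]] <- rbind(cbind(a, b[nxt_i], b),
                                         cbind(a, a[nxt_i], b[nxt_i]))
  }
  # wall: stacked outward quads from bottom to top
  levels_ids <- c(list(id_bot[outer_ids]), wall_levels, list(id_top[outer_ids]))
  for (l in seq_len(length(levels_ids) - 1L)) {
    lo <- levels_ids[[l]]
    hi <- levels_ids[[l + 1L]]
    faces[[length(faces) + 1L]] <- rbind(cbind(lo, lo[nxt_i], hi[nxt_i]),
                                         cbind(lo, hi[nxt_i], hi))
  }
  mesh <- trimesh(V, do.call(rbind, faces), clean = TRUE)
  if (!is_closed(mesh)) stop("nucleus solid construction failed to close")
  if (enclosed_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

# z-span (along dir) of a closed mesh above each base point; points whose
# ray misses are pulled toward `shrink_to` (2% steps) before giving up
.ray_span <- function(mesh, P, dir, shrink_to) {
  hits <- cpp_ray_all_hits(mesh$vertices, mesh$faces, P, dir)
  lo <- vapply(hits, function(h) if (length(h) >= 2L) h[1L] else NA_real_, 0)
  hi <- vapply(hits, function(h) if (length(h) >= 2L) h[length(h)] else NA_real_, 0)
  miss <- which(is.na(lo))
  for (i in miss) {
    p <- P[i, ]
    for (step in 1:10) {
      p <- p + 0.02 * (shrink_to[1L, ] - p)
      h <- cpp_ray_all_hits(mesh$vertices, mesh$faces, matrix(p, 1L), dir)[[1L]]
      if (length(h) >= 2L) {
        lo[i] <- h[1L]
        hi[i] <- h[length(h)]
        break
      }
    }
  }
  if (anyNA(lo)) stop("empty intersection: swept curve does not meet the disc")
  cbind(lo, hi)
}

#' Translate a mesh so its centroid matches a reference
#'
#' Rigid translation by `centroid(annulus_ref) - centroid(nucleus)`.
#'
#' @param nucleus [trimesh] to move.
#' @param annulus_ref reference [trimesh].
#' @export
align_centroids <- function(nucleus, annulus_ref) {
  translate_mesh(nucleus, centroid(annulus_ref) - centroid(nucleus))
}

#' Classify disc faces into annulus and nucleus sets
#'
#' A face belongs to the nucleus set iff at least one of its vertices lies
#' inside the nucleus solid; faces with all vertices outside are annulus.
#' The partition is exhaustive and exclusive by construction.
#'
#' @param disc disc [trimesh].
#' @param nucleus closed nucleus classifier [trimesh].
#' @return list with integer face-index vectors `annulus_faces`,
#'   `nucleus_faces` and the per-vertex logical `inside`.
#' @export
partition_disc_faces <- function(disc, nucleus) {
  inside <- point_in_mesh(nucleus, disc$vertices)
  F <- disc$faces
  any_in <- inside[F[, 1L]] | inside[F[, 2L]] | inside[F[, 3L]]
  list(annulus_faces = which(!any_in), nucleus_faces = which(any_in),
       inside = inside)
}

#' Split a face set at the mid z-threshold
#'
#' `z_threshold = (max z + min z) / 2` over face centroids, with z measured
#' along the frame's u3 axis; faces with centroid above the threshold go to
#' `top`.
#'
#' @param mesh the parent [trimesh].
#' @param face_idx integer face indices to split.
#' @param frame optional [pca_frame]; when NULL, global z is used.
#' @return list `top`, `bottom` (face indices) and `z_threshold`.
#' @export
split_top_bottom <- function(mesh, face_idx, frame = NULL) {
  if (length(face_idx) == 0L) stop("empty face set")
  F <- mesh$faces[face_idx, , drop = FALSE]
  cen <- (mesh$vertices[F[, 1L], , drop = FALSE] +
            mesh$vertices[F[, 2L], , drop = FALSE] +
            mesh$vertices[F[, 3L], , drop = FALSE]) / 3
  z <- if (is.null(frame)) cen[, 3L]
  else drop(sweep(cen, 2L, frame$mean) %*% frame$axes[, 3L])
  thr <- (max(z) + min(z)) / 2
  list(top = face_idx[z > thr], bottom = face_idx[z <= thr], z_threshold = thr)
}

#' Loft a triangulated wall between two corresponded closed curves
#'
#' Both curves must have the same number of points N. The correspondence is
#' the cyclic shift (optionally with direction reversal) of the second
#' curve minimizing the total squared distance; each of the N quads is then
#' split into two triangles.
#'
#' @param top_boundary,bottom_boundary [boundary_curve]s with equal counts.
#' @return a [trimesh] strip of `2 N` triangles, closed around the loop.
#' @export
loft_walls <- function(top_boundary, bottom_boundary) {
  Tc <- top_boundary$points
  Bc <- bottom_boundary$points
  if (nrow(Tc) != nrow(Bc))
    stop("curve point counts differ (", nrow(Tc), " vs ", nrow(Bc), ")")
  n <- nrow(Tc)
  best <- NULL
  bestd <- Inf
  for (rev_dir in c(FALSE, TRUE)) {
    Bv <- if (rev_dir) Bc[c(1L, n:2L), , drop = FALSE] else Bc
    for (k in 0:(n - 1L)) {
      idx <- ((seq_len(n) - 1L + k) %% n) + 1L
      d <- sum((Tc - Bv[idx, , drop = FALSE])^2)
      if (d < bestd) {
        bestd <- d
        best <- Bv[idx, , drop = FALSE]
      }
    }
  }
  Bal <- best
  V <- rbind(Tc, Bal)
  ti <- seq_len(n)
  bi <- n + seq_len(n)
  nx <- c(2:n, 1L)
  F <- rbind(cbind(bi, bi[nx], ti[nx]), cbind(bi, ti[nx], ti))
  m <- trimesh(V, F, clean = FALSE)
  ar <- .face_area(m$vertices, m$faces)
  if (any(ar < 1e-10))
    stop("degenerate loft triangles (curves coincide?)")
  m
}

# ---- stitching ---------------------------------------------------------

# Ordered boundary loops of a face subset, following face direction. At
# pinch vertices (4+ boundary edges) the successor is found by rotating
# around the vertex through the face fan, which keeps loops consistent.
.patch_boundary_loops <- function(mesh, face_idx) {
  F <- mesh$faces[face_idx, , drop = FALSE]
  nf <- nrow(F)
  da <- as.integer(F[, c(1L, 2L, 3L)])
  db <- as.integer(F[, c(2L, 3L, 1L)])
  dirmap <- new.env(hash = TRUE, size = 3L * nf)  # "a_b" -> face row
  for (i in seq_along(da)) assign(paste0(da[i], "_", db[i]),
                                  ((i - 1L) %% nf) + 1L, envir = dirmap)
  has_dir <- function(a, b) exists(paste0(a, "_", b), envir = dirmap,
                                   inherits = FALSE)
  face_of <- function(a, b) get(paste0(a, "_", b), envir = dirmap,
                                inherits = FALSE)
  is_boundary <- function(a, b) has_dir(a, b) && !has_dir(b, a)
  # successor of boundary edge (a -> b): rotate around b
  next_edge <- function(a, b) {
    f <- face_of(a, b)
    tri <- F[f, ]
    c_ <- tri[tri != a & tri != b][1L]
    repeat {
      if (is_boundary(b, c_)) return(c(b, c_))
      if (!has_dir(c_, b)) return(NULL)  # should not happen on manifold input
      f2 <- face_of(c_, b)
      tri2 <- F[f2, ]
      c_ <- tri2[tri2 != b & tri2 != c_][1L]
    }
  }
  bnd <- which(vapply(seq_along(da), function(i) !has_dir(db[i], da[i]), TRUE))
  used <- new.env(hash = TRUE)
  loops <- list()
  for (i in bnd) {
    key0 <- paste0(da[i], "_", db[i])
    if (exists(key0, envir = used, inherits = FALSE)) next
    loop <- integer(0)
    a <- da[i]
    b <- db[i]
    repeat {
      k <- paste0(a, "_", b)
      if (exists(k, envir = used, inherits = FALSE)) break
      assign(k, TRUE, envir = used)
      loop <- c(loop, a)
      nx <- next_edge(a, b)
      if (is.null(nx)) break
      a <- nx[1L]
      b <- nx[2L]
    }
    if (length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  loops[order(-vapply(loops, length, 0L))]
}

# greedy zipper triangulation between two closed 3-D loops (point matrices,
# both traversed in the same rotational sense); returns triangles as rows of
# vertex ids offset for A (1..na) and B (na+1..na+nb), wound (b, b_next, t)
.zipper <- function(A, B) {
  na <- nrow(A)
  nb <- nrow(B)
  j0 <- which.min(colSums((t(B) - A[1L, ])^2))
  tri <- matrix(0L, 0L, 3L)
  i <- 0L
  j <- 0L  # consumed counts
  ai <- function(k) ((k) %% na) + 1L
  bi <- function(k) ((k + j0 - 1L) %% nb) + 1L
  while (i < na || j < nb) {
    adv_a_cost <- if (i < na) sum((A[ai(i + 1L), ] - B[bi(j), ])^2) else Inf
    adv_b_cost <- if (j < nb) sum((B[bi(j + 1L), ] - A[ai(i), ])^2) else Inf
    if (adv_a_cost <= adv_b_cost) {
      tri <- rbind(tri, c(ai(i), ai(i + 1L), na + bi(j)))
      i <- i + 1L
    } else {
      tri <- rbind(tri, c(ai(i), na + bi(j + 1L), na + bi(j)))
      j <- j + 1L
    }
  }
  tri
}

#' Stitch nucleus and annulus into watertight sub-meshes and solids
#'
#' The nucleus face set is split into top and bottom caps, their boundary
#' loops are traced and joined by a nearest-neighbour zipper wall, giving a
#' watertight nucleus surface whose caps are actual disc faces. The annulus
#' surface is the annulus face set closed by the same wall with reversed
#' orientation (coincident interface nodes, duplicated between the two
#' parts for the stick-contact pair). The nucleus volume is meshed by
#' star-kernel fan; the annulus (an annular solid) by a structured swept
#' grid conforming to the wall nodes and the disc surface.
#'
#' @param disc disc [trimesh].
#' @param annulus_faces,nucleus_faces face-index partition from
#'   [partition_disc_faces()].
#' @param frame disc [pca_frame].
#' @param point_spacing grid spacing for the annulus solid, mm.
#' @return object of class `disc_partition`.
#' @export
stitch_annulus_nucleus <- function(disc, annulus_faces, nucleus_faces, frame,
                                   point_spacing = 1) {
  if (length(nucleus_faces) == 0L || length(annulus_faces) == 0L)
    stop("face partition has an empty side")
  sp <- split_top_bottom(disc, nucleus_faces, frame)
  if (length(sp$top) == 0L || length(sp$bottom) == 0L)
    stop("nucleus face set does not span top and bottom caps")
  lt <- .patch_boundary_loops(disc, sp$top)
  lb <- .patch_boundary_loops(disc, sp$bottom)
  if (length(lt) == 0L || length(lb) == 0L)
    stop("could not trace nucleus cap boundary loops")
  loop_t <- lt[[1L]]
  loop_b <- lb[[1L]]
  # orient both CCW when viewed from +u3
  ccw <- function(loop) {
    uv <- .to_frame(frame, disc$vertices[loop, , drop = FALSE])
    Q <- uv[c(2:nrow(uv), 1L), , drop = FALSE]
    if (0.5 * sum(uv[, 1L] * Q[, 2L] - Q[, 1L] * uv[, 2L]) < 0) rev(loop) else loop
  }
  loop_t <- ccw(loop_t)
  loop_b <- ccw(loop_b)
  At <- disc$vertices[loop_t, , drop = FALSE]
  Ab <- disc$vertices[loop_b, , drop = FALSE]
  wall_local <- .zipper(Ab, At)  # bottom loop = A side, top = B side
  wall_V <- rbind(Ab, At)
  wall <- trimesh(wall_V, wall_local, clean = FALSE)

  # nucleus surface: cap faces (disc orientation) + outward wall
  nuc_faces_global <- c(sp$top, sp$bottom)
  nucleus_mesh <- .merge_face_sets(disc, nuc_faces_global, wall)
  nucleus_mesh <- fill_holes(nucleus_mesh, max_perimeter = 10 * point_spacing)
  if (!is_closed(nucleus_mesh))
    stop("nucleus surface not watertight after stitching (",
         nrow(boundary_edges(nucleus_mesh)), " boundary edges)")
  if (enclosed_volume(nucleus_mesh) < 0)
    nucleus_mesh$faces <- nucleus_mesh$faces[, c(1L, 3L, 2L)]

  wall_rev <- wall
  wall_rev$faces <- wall_rev$faces[, c(1L, 3L, 2L)]
  annulus_mesh <- .merge_face_sets(disc, annulus_faces, wall_rev)
  annulus_mesh <- fill_holes(annulus_mesh, max_perimeter = 10 * point_spacing)
  if (!is_closed(annulus_mesh))
    stop("annulus surface not watertight after stitching (",
         nrow(boundary_edges(annulus_mesh)), " boundary edges)")
  if (enclosed_volume(annulus_mesh) < 0)
    annulus_mesh$faces <- annulus_mesh$faces[, c(1L, 3L, 2L)]

  nucleus_solid <- tetrahedralize(nucleus_mesh)
  # solid grid runs coarser than the surface sampling: resolution there is
  # set by the surface meshes, not the interior cells
  annulus_solid <- .annulus_swept_solid(disc, frame, loop_t, loop_b,
                                        2.5 * point_spacing)
  structure(list(annulus_faces = annulus_faces, nucleus_faces = nucleus_faces,
                 nucleus_mesh = nucleus_mesh, annulus_mesh = annulus_mesh,
                 nucleus_solid = nucleus_solid, annulus_solid = annulus_solid,
                 wall = wall, z_threshold = sp$z_threshold, frame = frame),
            class = "disc_partition")
}

#' @export
print.disc_partition <- function(x, ...) {
  cat(sprintf(paste0("disc_partition: %d nucleus + %d annulus faces; ",
                     "nucleus %.1f mm^3, annulus %.1f mm^3\n"),
              length(x$nucleus_faces), length(x$annulus_faces),
              tet_volume(x$nucleus_solid), tet_volume(x$annulus_solid)))
  invisible(x)
}

# merge a face subset of `mesh` with an extra surface, welding identical
# coordinates so shared boundary vertices fuse
.merge_face_sets <- function(mesh, face_idx, extra) {
  sub <- subset_faces(mesh, face_idx)
  V <- rbind(sub$vertices, extra$vertices)
  F <- rbind(sub$faces, extra$faces + nrow(sub$vertices))
  merge_vertices(trimesh(V, F, clean = FALSE), tol = 1e-9)
}

# structured swept tet mesh of the annular region between the nucleus wall
# (defined by the cap boundary loops) and the disc surface
.annulus_swept_solid <- function(disc, frame, loop_t, loop_b, spacing) {
  u3 <- frame$axes[, 3L]
  Tpts <- disc$vertices[loop_t, , drop = FALSE]
  Bpts <- disc$vertices[loop_b, , drop = FALSE]
  cen_uv <- colMeans(.to_frame(frame, rbind(Tpts, Bpts)))
  # Stations follow the loops by normalized arc length (after aligning the
  # bottom loop's start to the top loop's), so the jagged cap boundaries
  # are tracked exactly: every loop vertex becomes a wall node with its
  # exact coordinates and the wall matches the zipper ruling.
  j0 <- which.min(colSums((t(Bpts) - Tpts[1L, ])^2))
  Bpts <- Bpts[c(j0:nrow(Bpts), seq_len(j0 - 1L)), , drop = FALSE]
  arcpar <- function(P) {
    seg <- sqrt(rowSums((P[c(2:nrow(P), 1L), , drop = FALSE] - P)^2))
    c(0, cumsum(seg))[seq_len(nrow(P))] / sum(seg)
  }
  pt <- arcpar(Tpts)
  pb <- arcpar(Bpts)
  tpar <- sort(unique(c(pt, pb)))
  ns <- length(tpar)
  polyline_at <- function(P, par, t) {
    hit <- match(TRUE, abs(par - t) < 1e-12)
    if (!is.na(hit)) return(P[hit, ])
    i0 <- findInterval(t, par)
    i1 <- if (i0 == nrow(P)) 1L else i0 + 1L
    t1 <- if (i0 == nrow(P)) 1 else par[i1]
    w <- (t - par[i0]) / (t1 - par[i0])
    (1 - w) * P[i0, ] + w * P[i1, ]
  }
  topP <- t(vapply(tpar, function(t) polyline_at(Tpts, pt, t), numeric(3L)))
  botP <- t(vapply(tpar, function(t) polyline_at(Bpts, pb, t), numeric(3L)))
  hmean <- mean(sqrt(rowSums((topP - botP)^2)))
  # outer extent at mid height per station (radial ray in the frame plane)
  midP <- (topP + botP) / 2
  uv_mid <- .to_frame(frame, midP)
  rad_dir <- sweep(uv_mid, 2L, cen_uv)
  rad_dir <- rad_dir / sqrt(rowSums(rad_dir^2))
  dir3 <- rad_dir %*% t(frame$axes[, 1:2, drop = FALSE])
  outer_t <- vapply(seq_len(ns), function(s) {
    h <- cpp_ray_all_hits(disc$vertices, disc$faces, midP[s, , drop = FALSE],
                          dir3[s, ])[[1L]]
    h <- h[h > 1e-9]
    if (length(h) == 0L) NA_real_ else h[length(h)]
  }, 0)
  if (anyNA(outer_t)) stop("annulus sweep: radial ray missed the disc surface")
  Mrad <- max(2L, as.integer(ceiling(stats::median(outer_t) / spacing)))
  # the l-dimension follows the outer cross-section chain (wall top -> cap
  # -> rim -> cap -> wall bottom), which is much longer than the wall
  K <- max(4L, as.integer(ceiling((hmean + 2 * stats::median(outer_t)) / spacing)))
  # Per station, the outer boundary of the (radial, axial) cross-section is
  # traced by rays from a mid-annulus point: it runs from the wall top,
  # over the cap and rim, to the wall bottom, so the steep lateral wall and
  # rim rounding are sampled directly. The grid is transfinite between the
  # wall column and that boundary chain (corners degenerate; the zero-
  # volume cells there are dropped).
  n_chain_rays <- 2L * K + 3L
  nid <- array(0L, dim = c(ns, K + 1L, Mrad + 1L))
  Vl <- list()
  vcount <- 0L
  add_v <- function(p) {
    vcount <<- vcount + 1L
    Vl[[vcount]] <<- p
    vcount
  }
  for (s in seq_len(ns)) {
    wallpts <- outer(seq(0, 1, length.out = K + 1L), botP[s, ] - topP[s, ]) +
      matrix(topP[s, ], K + 1L, 3L, byrow = TRUE)
    cs <- midP[s, ] + 0.5 * outer_t[s] * dir3[s, ]
    loc <- function(p) c(sum((p - cs) * dir3[s, ]), sum((p - cs) * u3))
    a_top <- do.call(atan2, as.list(rev(loc(topP[s, ]))))
    a_bot <- do.call(atan2, as.list(rev(loc(botP[s, ]))))
    if (a_bot > a_top - 1e-9) a_bot <- a_bot - 2 * pi
    alphas <- seq(a_top, a_bot, length.out = n_chain_rays + 2L)
    alphas <- alphas[-c(1L, length(alphas))]
    dirs <- outer(cos(alphas), dir3[s, ]) + outer(sin(alphas), u3)
    th <- cpp_first_hit_along(disc$vertices, disc$faces,
                              matrix(cs, length(alphas), 3L, byrow = TRUE),
                              dirs, 1e-9)
    ok <- is.finite(th)
    chain <- rbind(topP[s, ], dirs[ok, , drop = FALSE] * th[ok] +
                     matrix(cs, sum(ok), 3L, byrow = TRUE), botP[s, ])
    outer_pts <- .resample_open(chain, K + 1L)
    for (l in 0:K) {
      nid[s, l + 1L, 1L] <- add_v(wallpts[l + 1L, ])
      for (m in seq_len(Mrad)) {
        w <- m / Mrad
        nid[s, l + 1L, m + 1L] <-
          add_v((1 - w) * wallpts[l + 1L, ] + w * outer_pts[l + 1L, ])
      }
    }
  }
  V <- do.call(rbind, Vl)
  # hexes -> 12 tets via face-centroid-free split: centroid point per hex,
  # quad faces split along the diagonal from their smallest node id
  cells <- list()
  extraV <- list()
  nxt_s <- c(2:ns, 1L)
  for (s in seq_len(ns)) {
    s2 <- nxt_s[s]
    for (l in seq_len(K)) {
      for (m in seq_len(Mrad)) {
        corner <- c(nid[s, l, m], nid[s2, l, m], nid[s2, l + 1L, m], nid[s, l + 1L, m],
                    nid[s, l, m + 1L], nid[s2, l, m + 1L], nid[s2, l + 1L, m + 1L],
                    nid[s, l + 1L, m + 1L])
        cp <- colMeans(V[corner, , drop = FALSE])
        extraV[[length(extraV) + 1L]] <- cp
        ci <- nrow(V) + length(extraV)
        quads <- rbind(c(1L, 2L, 3L, 4L), c(5L, 6L, 7L, 8L),
                       c(1L, 2L, 6L, 5L), c(2L, 3L, 7L, 6L),
                       c(3L, 4L, 8L, 7L), c(4L, 1L, 5L, 8L))
        for (q in seq_len(6L)) {
          ids <- corner[quads[q, ]]
          k0 <- which.min(ids)
          a <- ids[k0]
          b <- ids[(k0 %% 4L) + 1L]
          cc <- ids[((k0 + 1L) %% 4L) + 1L]
          d <- ids[((k0 + 2L) %% 4L) + 1L]
          cells[[length(cells) + 1L]] <- rbind(c(a, b, cc, ci), c(a, cc, d, ci))
        }
      }
    }
  }
  Vfull <- rbind(V, do.call(rbind, extraV))
  C <- do.call(rbind, cells)
  tetmesh(Vfull, C)
}

# closed capped prism: the scaled curve extruded between two u3 offsets
# (the unclipped extrusion used for membership classification)
.capped_prism <- function(curve, z_lo, z_hi) {
  frame <- curve$frame
  uv <- .to_frame(frame, curve$points)
  c2 <- colMeans(uv)
  u3 <- frame$axes[, 3L]
  base <- .from_frame(frame, uv)
  cen <- .from_frame(frame, matrix(c2, 1L, 2L))
  n <- nrow(uv)
  V <- rbind(sweep(base, 2L, z_lo * u3, "+"),
             sweep(base, 2L, z_hi * u3, "+"),
             cen + z_lo * u3, cen + z_hi * u3)
  lo <- seq_len(n)
  hi <- n + seq_len(n)
  cl <- 2L * n + 1L
  ch <- 2L * n + 2L
  nx <- c(2:n, 1L)
  F <- rbind(cbind(lo, lo[nx], hi[nx]), cbind(lo, hi[nx], hi),  # wall
             cbind(ch, hi, hi[nx]),                              # top cap
             cbind(cl, lo[nx], lo))                              # bottom cap
  m <- trimesh(V, F, clean = TRUE)
  if (enclosed_volume(m) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

#' Full nucleus/annulus separation of one disc
#'
#' Runs the whole chain: PCA frame, boundary curve, curve scaling, swept
#' nucleus solid, centroid alignment, face partition and stitching. Face
#' membership is classified against the unclipped extrusion of the scaled
#' curve (spanning the disc extent plus a 5% margin): the clipped solid's
#' caps lie exactly on the disc surface, which would make cap-vertex
#' membership numerically ill-posed, while the extrusion yields the same
#' cylinder-footprint membership with a strict margin.
#'
#' @param disc closed disc [trimesh].
#' @param scale nucleus scale factor (default 0.6; nucleus cross-section
#'   about 36% of the disc's).
#' @param point_spacing sampling/grid spacing, mm.
#' @param n_samples boundary-curve samples.
#' @return a `disc_partition` (the clipped swept solid is attached as
#'   `$clipped_cylinder`).
#' @export
split_disc <- function(disc, scale = 0.6, point_spacing = 1, n_samples = 64L) {
  frame <- pca_frame(disc$vertices)
  curve <- disc_boundary_curve(disc, frame, n_samples)
  scaled <- scale_curve(curve, scale)
  clipped <- build_nucleus_solid(scaled, disc, point_spacing)
  clipped <- align_centroids(clipped, disc)
  w <- drop(sweep(disc$vertices, 2L, frame$mean) %*% frame$axes[, 3L])
  margin <- 0.05 * (max(w) - min(w))
  classifier <- .capped_prism(scaled, min(w) - margin, max(w) + margin)
  part <- partition_disc_faces(disc, classifier)
  if (length(part$nucleus_faces) == 0L)
    stop("nucleus classifier captured no disc faces; increase scale")
  out <- stitch_annulus_nucleus(disc, part$annulus_faces, part$nucleus_faces,
                                frame, point_spacing)
  out$clipped_cylinder <- clipped
  out
}
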