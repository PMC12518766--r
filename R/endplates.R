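#' Endplate extraction parameters
#'
#' Thresholds of the four-step endplate recipe: clustering distance
#' (1.5 mm), upper radial-percentile cut (70th, linear-interpolation
#' definition), lower-plane offset (20 mm) and lower radial retention
#' fraction (55% of the maximum radius).
#'
#' @param cluster_dist single-linkage clustering cutoff, mm.
#' @param upper_keep_percentile radial percentile kept for the upper patch.
#' @param lower_offset distance of the lower cutting plane below the upper
#'   endplate plane, mm.
#' @param lower_keep_fraction fraction of the maximum radial distance kept
#'   for the lower patch.
#' @export
endplate_params <- function(cluster_dist = 1.5, upper_keep_percentile = 70,
                            lower_offset = 20, lower_keep_fraction = 0.55) {
  if (cluster_dist <= 0 || lower_offset <= 0) stop("distances must be positive")
  if (upper_keep_percentile <= 0 || upper_keep_percentile > 100)
    stop("upper_keep_percentile must be in (0, 100]")
  if (lower_keep_fraction <= 0 || lower_keep_fraction > 1)
    stop("lower_keep_fraction must be in (0, 1]")
  structure(list(cluster_dist = cluster_dist,
                 upper_keep_percentile = upper_keep_percentile,
                 lower_offset = lower_offset,
                 lower_keep_fraction = lower_keep_fraction),
            class = "endplate_params")
}

#' Light direction of a vertebra
#'
#' The least-variance principal axis of the vertex cloud, sign-fixed toward
#' global +z. Faces whose normal has a positive dot product with it are
#' "upward facing".
#'
#' @param vertebra a [trimesh] (>= 4 vertices).
#' @return unit length-3 vector.
#' @export
light_direction <- function(vertebra) {
  if (nrow(vertebra$vertices) < 4L) stop("need at least 4 vertices")
  fr <- pca_frame(vertebra$vertices)
  if (!all(is.finite(fr$axes))) stop("degenerate vertex cloud")
  fr$axes[, 3L]
}

# single-linkage clusters at a distance cutoff; returns labels
.cluster_at <- function(points, cutoff) cpp_cluster_points(points, cutoff)

#' Radial shrink filters for endplate refinement
#'
#' Radii are measured from the point-set centroid in the plane orthogonal
#' to the light direction `L` (Euclidean distance of the projected offset).
#' `radial_keep_percentile` retains points whose radius does not exceed the
#' given percentile of all radii (linear interpolation between order
#' statistics); `radial_keep_fraction` retains points within the given
#' fraction of the maximum radius.
#'
#' @param points `n x 3` matrix.
#' @param L unit light direction.
#' @param percentile percentile in (0, 100].
#' @return logical keep vector of length `n`.
#' @export
radial_keep_percentile <- function(points, L, percentile) {
  r <- .planar_radii(as.matrix(points), L)
  r <= stats::quantile(r, percentile / 100, type = 7L, names = FALSE)
}

#' @rdname radial_keep_percentile
#' @param fraction fraction of the maximum radius in (0, 1].
#' @export
radial_keep_fraction <- function(points, L, fraction) {
  r <- .planar_radii(as.matrix(points), L)
  r <= fraction * max(r)
}

# planar radial distances about the cluster centroid, measured orthogonally
# to the light direction L
.planar_radii <- function(points, L) {
  cen <- colMeans(points)
  d <- sweep(points, 2L, cen)
  d_perp <- d - outer(drop(d %*% L), L)
  sqrt(rowSums(d_perp^2))
}

.fit_plane <- function(points, L) {
  cen <- colMeans(points)
  n <- if (nrow(points) >= 3L) {
    e <- eigen(crossprod(sweep(points, 2L, cen)), symmetric = TRUE)
    v <- e$vectors[, 3L]
    if (sum(v * L) < 0) -v else v
  } else L
  list(point = cen, normal = n / sqrt(sum(n^2)))
}

.make_patch <- function(mesh, keep_idx, L, sign) {
  F <- mesh$faces
  inset <- matrix(F %in% keep_idx, ncol = 3L)
  fkeep <- which(rowSums(inset) == 3L)
  pts <- mesh$vertices[keep_idx, , drop = FALSE]
  pl <- .fit_plane(pts, sign * L)
  pm <- if (length(fkeep) > 0L) {
    used <- sort(unique(as.integer(F[fkeep, , drop = FALSE])))
    remap <- integer(nrow(mesh$vertices))
    remap[used] <- seq_along(used)
    trimesh(mesh$vertices[used, , drop = FALSE],
            matrix(remap[F[fkeep, , drop = FALSE]], ncol = 3L), clean = FALSE)
  } else NULL
  structure(list(vertex_indices = keep_idx, faces = F[fkeep, , drop = FALSE],
                 face_indices = fkeep, plane = pl, centroid = colMeans(pts),
                 light = L, side = if (sign > 0) "upper" else "lower",
                 mesh = pm),
            class = "endplate_patch")
}

#' @export
print.endplate_patch <- function(x, ...) {
  cat(sprintf("endplate_patch (%s): %d vertices, %d faces, centroid (%.1f, %.1f, %.1f)\n",
              x$side, length(x$vertex_indices), nrow(x$faces),
              x$centroid[1L], x$centroid[2L], x$centroid[3L]))
  invisible(x)
}

#' Extract the upper endplate patch of a vertebra
#'
#' Four steps, in order: (1) keep vertices of upward faces
#' (`normal . L > 0`); (2) keep those above the mid z-threshold
#' `(max z + min z)/2` (z along L); (3) single-linkage cluster at
#' `cluster_dist` and keep the largest cluster (ties by larger z-mean);
#' (4) radial shrink: drop vertices whose in-plane radius from the cluster
#' centroid exceeds the `upper_keep_percentile`th percentile (linear
#' interpolation between order statistics). Patch faces are the triangles
#' with all three vertices retained.
#'
#' @param vertebra closed vertebra [trimesh].
#' @param params an [endplate_params].
#' @return an `endplate_patch`.
#' @export
extract_upper_endplate <- function(vertebra, params = endplate_params()) {
  stopifnot(inherits(params, "endplate_params"))
  L <- light_direction(vertebra)
  N <- face_normals(vertebra)
  up_faces <- which(drop(N %*% L) > 0)
  cand <- sort(unique(as.integer(vertebra$faces[up_faces, ])))
  z <- drop(vertebra$vertices %*% L)
  zthr <- (max(z) + min(z)) / 2
  cand <- cand[z[cand] > zthr]
  if (length(cand) == 0L) stop("empty upper-endplate candidate set")
  lab <- .cluster_at(vertebra$vertices[cand, , drop = FALSE], params$cluster_dist)
  sizes <- tabulate(lab)
  big <- which(sizes == max(sizes))
  if (length(big) > 1L) {
    zm <- vapply(big, function(k) mean(z[cand[lab == k]]), 0)
    big <- big[which.max(zm)]
  }
  cand <- cand[lab == big[1L]]
  keep <- cand[radial_keep_percentile(vertebra$vertices[cand, , drop = FALSE],
                                      L, params$upper_keep_percentile)]
  .make_patch(vertebra, keep, L, +1)
}

#' Extract the lower endplate patch of a vertebra
#'
#' A plane parallel to the upper endplate plane, `lower_offset` mm below it
#' along the light direction, bounds the candidates: vertices on its far
#' side (opposite the upper patch) that belong to downward faces
#' (`normal . L < 0`). The largest cluster at `cluster_dist` is kept and
#' radially shrunk to `lower_keep_fraction` of the maximum radius.
#'
#' @param vertebra closed vertebra [trimesh].
#' @param upper the upper `endplate_patch`.
#' @param params an [endplate_params].
#' @return an `endplate_patch`.
#' @export
extract_lower_endplate <- function(vertebra, upper,
                                   params = endplate_params()) {
  stopifnot(inherits(params, "endplate_params"))
  L <- upper$light
  plane_pt <- upper$plane$point - params$lower_offset * L
  N <- face_normals(vertebra)
  down_faces <- which(drop(N %*% L) < 0)
  cand <- sort(unique(as.integer(vertebra$faces[down_faces, ])))
  side <- drop(sweep(vertebra$vertices, 2L, plane_pt) %*% L)
  cand <- cand[side[cand] < 0]
  if (length(cand) == 0L)
    stop("no vertices below the lower cutting plane; vertebra shorter than ",
         params$lower_offset, " mm along L - reduce lower_offset")
  lab <- .cluster_at(vertebra$vertices[cand, , drop = FALSE], params$cluster_dist)
  sizes <- tabulate(lab)
  big <- which(sizes == max(sizes))
  if (length(big) > 1L) {
    zm <- vapply(big, function(k) mean(drop(vertebra$vertices[cand[lab == k], , drop = FALSE] %*% L)), 0)
    big <- big[which.min(zm)]
  }
  cand <- cand[lab == big[1L]]
  keep <- cand[radial_keep_fraction(vertebra$vertices[cand, , drop = FALSE],
                                    L, params$lower_keep_fraction)]
  .make_patch(vertebra, keep, L, -1)
}

#' Both endplates of a vertebra
#' @param vertebra closed vertebra [trimesh].
#' @param params an [endplate_params].
#' @return list with `upper` and `lower` patches.
#' @export
extract_endplates <- function(vertebra, params = endplate_params()) {
  upper <- extract_upper_endplate(vertebra, params)
  lower <- extract_lower_endplate(vertebra, upper, params)
  list(upper = upper, lower = lower)
}

# patch as standalone mesh (compact indexing)
.patch_mesh <- function(vertebra, patch) {
  if (nrow(patch$faces) == 0L) stop("endplate patch has no complete faces")
  used <- sort(unique(as.integer(patch$faces)))
  remap <- integer(nrow(vertebra$vertices))
  remap[used] <- seq_along(used)
  trimesh(vertebra$vertices[used, , drop = FALSE],
          matrix(remap[patch$faces], ncol = 3L), clean = FALSE)
}
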