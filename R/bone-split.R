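#' Bone-split parameters
#'
#' Uniform cortical thickness `t_core` (default 0.3 mm), the Laplacian
#' smoothing applied to the offset core, and an optional isotropic remesh
#' target applied to the outer surface before offsetting.
#'
#' @param t_core cortical shell thickness, mm (> 0).
#' @param smoothing a [smoothing_params] (default lam 0.5, 10 iterations).
#' @param remesh_edge optional target edge length for pre-remeshing, mm.
#' @export
bone_split_params <- function(t_core = 0.3, smoothing = smoothing_params(0.5, 10L),
                              remesh_edge = NULL) {
  if (!is.numeric(t_core) || length(t_core) != 1L || t_core <= 0)
    stop("t_core must be a positive thickness (mm)")
  stopifnot(inherits(smoothing, "smoothing_params"))
  if (!is.null(remesh_edge) && remesh_edge <= 0) stop("remesh_edge must be > 0")
  structure(list(t_core = t_core, smoothing = smoothing,
                 remesh_edge = remesh_edge), class = "bone_split_params")
}

#' Inward surface offset along vertex normals
#'
#' Moves every vertex inward by `t_core` along its area-weighted vertex
#' normal (`V_cancellous = V_cortical - t_core * n(v)`), copying the
#' connectivity. A thin-feature guard clamps the local offset to 45% of the
#' opposite-wall distance wherever the inward ray meets the far surface
#' within `2 * t_core`, which prevents inversion at thin posterior
#' processes.
#'
#' @param mesh closed outward-oriented [trimesh].
#' @param t_core offset distance, mm (0 returns the mesh unchanged).
#' @return a [trimesh] with identical connectivity.
#' @export
offset_inward <- function(mesh, t_core) {
  nb <- nrow(boundary_edges(mesh))
  if (nb > 0L) stop("mesh is open (", nb, " boundary edges); offset undefined")
  if (t_core < 0) stop("t_core must be >= 0")
  if (t_core == 0) return(mesh)
  n <- vertex_normals(mesh)
  # thin-region guard: distance to the opposite wall along -n
  d <- rep(t_core, nrow(mesh$vertices))
  opp <- cpp_first_hit_along(mesh$vertices, mesh$faces, mesh$vertices, -n, 1e-6)
  clamp <- which(is.finite(opp) & opp < 2 * t_core)
  if (length(clamp) > 0L) {
    d[clamp] <- 0.45 * opp[clamp]
    attr(mesh, "clamped_vertices") <- clamp
  }
  out <- mesh
  out$vertices <- mesh$vertices - n * d
  out
}

#' Extract the cancellous (inner) surface of a vertebra
#'
#' Inward offset by `t_core` followed by Laplacian smoothing to remove the
#' sharp features and local self-intersections the raw offset can create.
#' If the smoothed surface still self-intersects, smoothing is retried once
#' with 50% more iterations before giving up. Optionally remeshed to
#' `params$remesh_edge` afterwards.
#'
#' @param mesh closed outward-oriented vertebra [trimesh].
#' @param params a [bone_split_params].
#' @return closed, self-intersection-free [trimesh].
#' @export
extract_cancellous <- function(mesh, params = bone_split_params()) {
  stopifnot(inherits(params, "bone_split_params"))
  core <- offset_inward(mesh, params$t_core)
  sm <- params$smoothing
  core_s <- laplacian_smooth(core, sm)
  if (nrow(self_intersections(core_s, 1L)) > 0L) {
    sm2 <- smoothing_params(sm$lam, ceiling(sm$iterations * 1.5))
    core_s <- laplacian_smooth(core, sm2)
    if (nrow(self_intersections(core_s, 1L)) > 0L)
      stop("offset surface still self-intersects after retry; ",
           "increase lam/iterations or reduce t_core")
  }
  core_s <- .pull_inside(mesh, core_s, core$vertices)
  if (!is.null(params$remesh_edge))
    core_s <- remesh_isotropic(core_s, params$remesh_edge)
  if (!is_closed(core_s)) stop("cancellous surface is not closed")
  core_s
}

# smoothing can push vertices back out through the outer wall at concave
# creases; blend offenders toward their raw-offset position (inside by
# construction) until the whole core is contained
.pull_inside <- function(outer, core, raw_offset) {
  for (it in 1:12) {
    out_idx <- which(!point_in_mesh(outer, core$vertices))
    if (length(out_idx) == 0L) return(core)
    w <- if (it >= 8L) 1 else 0.5
    core$vertices[out_idx, ] <-
      (1 - w) * core$vertices[out_idx, , drop = FALSE] +
      w * raw_offset[out_idx, , drop = FALSE]
  }
  out_idx <- which(!point_in_mesh(outer, core$vertices))
  if (length(out_idx) > 0L)
    stop("could not pull ", length(out_idx),
         " offset vertices back inside the outer surface; reduce t_core")
  core
}

#' Build the cortical shell and cancellous core volumes
#'
#' Conforming tetrahedralization of the outer volume: when `outer` and
#' `core` share connectivity (the standard offset path) the shell is meshed
#' as a prism layer between matched triangles (3 tets per prism) and the
#' core by star-kernel fan, so cells classify exactly as shell (centroid
#' outside the core) or core (inside) and the interface nodes are shared
#' without duplication: shell nodes are `[outer vertices; core vertices]`
#' and core nodes reuse the same core vertex coordinates.
#'
#' @param outer closed outer (cortical) [trimesh].
#' @param core closed inner (cancellous) [trimesh], strictly inside `outer`.
#' @return list with `cortical_shell` and `cancellous_core` ([tetmesh]es).
#' @export
build_cortical_shell <- function(outer, core) {
  inside <- point_in_mesh(outer, core$vertices)
  if (!all(inside))
    stop("core vertices outside the outer surface: ",
         paste(head(which(!inside), 10L), collapse = ", "))
  if (nrow(outer$faces) != nrow(core$faces) ||
      !all(outer$faces == core$faces))
    stop("outer and core connectivity differ; offset before remeshing ",
         "(or remesh the outer surface first) so the surfaces correspond")
  nv <- nrow(outer$vertices)
  Vshell <- rbind(outer$vertices, core$vertices)
  # prism layer between matched outer/inner triangles; conforming quad
  # diagonals (see .prism_cells)
  shell <- tetmesh(Vshell, .prism_cells(outer$faces, nv))
  corem <- tetrahedralize(core)
  list(cortical_shell = shell, cancellous_core = corem)
}

#' Full cortical/cancellous split of one vertebra
#'
#' Remeshes the outer surface when requested, extracts the cancellous
#' surface, and builds both volumes. Returns the surfaces and tet meshes.
#'
#' @param mesh closed vertebra [trimesh].
#' @param params a [bone_split_params].
#' @return object of class `bone_split` with `cortical_outer`,
#'   `cancellous_surface`, `cortical_shell`, `cancellous_core`.
#' @export
split_vertebra <- function(mesh, params = bone_split_params()) {
  stopifnot(inherits(params, "bone_split_params"))
  outer <- mesh
  if (!is.null(params$remesh_edge)) {
    outer <- remesh_isotropic(outer, params$remesh_edge)
    params <- bone_split_params(params$t_core, params$smoothing, NULL)
  }
  core <- extract_cancellous(outer, params)
  vols <- build_cortical_shell(outer, core)
  structure(list(cortical_outer = outer, cancellous_surface = core,
                 cortical_shell = vols$cortical_shell,
                 cancellous_core = vols$cancellous_core),
            class = "bone_split")
}

#' @export
print.bone_split <- function(x, ...) {
  vo <- enclosed_volume(x$cortical_outer)
  vs <- tet_volume(x$cortical_shell)
  vc <- tet_volume(x$cancellous_core)
  cat(sprintf(paste0("bone_split: outer %.1f mm^3 = shell %.1f + core %.1f ",
                     "(closure %.2f%%)\n"), vo, vs, vc, 100 * (vs + vc) / vo))
  invisible(x)
}
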