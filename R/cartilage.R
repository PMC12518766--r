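#' Disc faces in contact with an endplate
#'
#' Faces of a disc part (nucleus or annulus surface) whose centroid lies
#' within `max_gap` of the endplate patch surface and on the side the
#' endplate faces (positive side of the patch plane, whose normal points
#' from the vertebra toward the disc).
#'
#' @param disc_part [trimesh] (nucleus or annulus surface).
#' @param endplate an `endplate_patch`.
#' @param max_gap distance threshold, mm (> 0).
#' @return integer face indices into `disc_part$faces` (possibly empty,
#'   with a warning).
#' @export
contact_faces <- function(disc_part, endplate, max_gap = 2) {
  if (max_gap <= 0) stop("max_gap must be > 0")
  if (is.null(endplate$mesh)) stop("endplate patch has no faces")
  F <- disc_part$faces
  cen <- (disc_part$vertices[F[, 1L], , drop = FALSE] +
            disc_part$vertices[F[, 2L], , drop = FALSE] +
            disc_part$vertices[F[, 3L], , drop = FALSE]) / 3
  d <- cpp_dist_to_mesh(endplate$mesh$vertices, endplate$mesh$faces, cen)
  side <- drop(sweep(cen, 2L, endplate$plane$point) %*% endplate$plane$normal)
  out <- which(d <= max_gap & side > 0)
  if (length(out) == 0L)
    warning("no contact faces within ", max_gap, " mm of the ",
            endplate$side, " endplate")
  out
}

# conforming prism layer between matched triangle sheets: top ids = F,
# bottom ids = F + nv; quad diagonals leave the smallest vertex index
.prism_cells <- function(F, nv) {
  rot <- max.col(-F, ties.method = "first")
  n_f <- nrow(F)
  idx <- cbind(rot, rot %% 3L + 1L, (rot + 1L) %% 3L + 1L)
  a <- F[cbind(seq_len(n_f), idx[, 1L])]
  b <- F[cbind(seq_len(n_f), idx[, 2L])]
  cc <- F[cbind(seq_len(n_f), idx[, 3L])]
  ai <- a + nv; bi <- b + nv; ci <- cc + nv
  swap <- cc < b
  rbind(cbind(a, b, cc, ifelse(swap, bi, ci)),
        cbind(a, ifelse(swap, bi, b), ifelse(swap, cc, ci), ifelse(swap, ci, bi)),
        cbind(a, bi, ci, ai))
}

#' Build one cartilage segment between an endplate and a disc
#'
#' The endplate patch is projected along its plane normal onto the contact
#' sub-mesh of the disc (union of the nucleus and annulus contact faces);
#' patch faces whose projection rays miss the disc or exceed `max_gap` are
#' trimmed away. The swept prisms between the patch and its projection are
#' cut into tetrahedra, filling the vertebra--disc gap exactly; the segment
#' surface is the closed boundary of that solid.
#'
#' @param endplate an `endplate_patch`.
#' @param nucleus_part,annulus_part the disc part surfaces.
#' @param nucleus_contact,annulus_contact face-index sets from
#'   [contact_faces()] (at least one non-empty).
#' @param label segment label, e.g. `"L1D1"`.
#' @param max_gap maximum projection distance, mm.
#' @return object of class `cartilage_segment`: `label`, `surface`
#'   ([trimesh]), `solid` ([tetmesh]), `patch_faces`.
#' @export
build_cartilage <- function(endplate, nucleus_part, nucleus_contact,
                            annulus_part, annulus_contact,
                            label = "cartilage", max_gap = 2) {
  if (length(nucleus_contact) == 0L && length(annulus_contact) == 0L)
    stop("both contact face sets are empty for segment ", label)
  target_faces <- list()
  target_verts <- list()
  off <- 0L
  for (pp in list(list(nucleus_part, nucleus_contact),
                  list(annulus_part, annulus_contact))) {
    if (length(pp[[2L]]) == 0L) next
    sub <- subset_faces(pp[[1L]], pp[[2L]])
    target_faces[[length(target_faces) + 1L]] <- sub$faces + off
    target_verts[[length(target_verts) + 1L]] <- sub$vertices
    off <- off + nrow(sub$vertices)
  }
  target <- trimesh(do.call(rbind, target_verts), do.call(rbind, target_faces),
                    clean = FALSE)
  pm <- endplate$mesh
  if (is.null(pm)) stop("endplate patch has no faces")
  n <- endplate$plane$normal
  dirs <- matrix(n, nrow(pm$vertices), 3L, byrow = TRUE)
  t_hit <- cpp_first_hit_along(target$vertices, target$faces, pm$vertices,
                               dirs, 0)
  ok_v <- is.finite(t_hit) & t_hit <= max_gap
  keepf <- which(ok_v[pm$faces[, 1L]] & ok_v[pm$faces[, 2L]] & ok_v[pm$faces[, 3L]])
  if (length(keepf) == 0L)
    stop("no endplate faces project onto the disc within max_gap for ", label)
  sub <- subset_faces(pm, keepf)
  used <- sort(unique(as.integer(pm$faces[keepf, , drop = FALSE])))
  th <- t_hit[used]
  Vtop <- sub$vertices
  Vbot <- Vtop + outer(th, n)
  nv <- nrow(Vtop)
  cells <- .prism_cells(sub$faces, nv)
  solid <- tetmesh(rbind(Vtop, Vbot), cells)
  surface <- tet_surface(solid)
  if (!is_closed(surface)) stop("cartilage surface failed to close for ", label)
  structure(list(label = label, surface = surface, solid = solid,
                 patch_faces = keepf,
                 nucleus_contact = nucleus_contact,
                 annulus_contact = annulus_contact,
                 mean_gap = mean(th)),
            class = "cartilage_segment")
}

#' @export
print.cartilage_segment <- function(x, ...) {
  cat(sprintf("cartilage_segment %s: %.1f mm^3, mean gap %.2f mm\n",
              x$label, tet_volume(x$solid), x$mean_gap))
  invisible(x)
}

#' All cartilage segments of a lumbar stack
#'
#' Two segments per disc: the lower endplate of the vertebra above
#' (`LkDk`) and the upper endplate of the vertebra below (`L(k+1)Dk`),
#' giving the labels L1D1, L2D1, L2D2, ..., L5D4 for a 5-level stack.
#'
#' @param endplates named list (`L1`..) of `extract_endplates()` results.
#' @param discs named list (`D1`..) of `disc_partition`s.
#' @param max_gap contact/projection threshold, mm.
#' @return named list of `cartilage_segment`s.
#' @export
build_all_cartilage <- function(endplates, discs, max_gap = 2) {
  out <- list()
  nd <- length(discs)
  for (k in seq_len(nd)) {
    dk <- discs[[paste0("D", k)]]
    for (side in 1:2) {
      lev <- if (side == 1L) k else k + 1L
      patch <- if (side == 1L) endplates[[paste0("L", lev)]]$lower
      else endplates[[paste0("L", lev)]]$upper
      label <- sprintf("L%dD%d", lev, k)
      nc <- suppressWarnings(contact_faces(dk$nucleus_mesh, patch, max_gap))
      ac <- suppressWarnings(contact_faces(dk$annulus_mesh, patch, max_gap))
      out[[label]] <- build_cartilage(patch, dk$nucleus_mesh, nc,
                                      dk$annulus_mesh, ac, label, max_gap)
    }
  }
  out
}
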