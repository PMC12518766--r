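#' Material card
#'
#' One constitutive definition: isotropic elastic (E MPa, nu), two-parameter
#' Mooney--Rivlin (c1, c2, bulk MPa), rigid body, or linear spring (E MPa,
#' converted to per-spring stiffness k = E A / L at export).
#'
#' @param name card name.
#' @param model one of `"isotropic_elastic"`, `"mooney_rivlin"`, `"rigid"`,
#'   `"linear_spring"`.
#' @param E Young's modulus, MPa.
#' @param nu Poisson's ratio.
#' @param c1,c2,bulk Mooney--Rivlin parameters, MPa.
#' @param density g/cm^3.
#' @export
material_card <- function(name, model, E = NULL, nu = NULL, c1 = NULL,
                          c2 = NULL, bulk = NULL, density = NULL) {
  model <- match.arg(model, c("isotropic_elastic", "mooney_rivlin", "rigid",
                              "linear_spring"))
  if (model == "isotropic_elastic") {
    if (is.null(E) || E <= 0) stop("isotropic card needs E > 0")
    if (is.null(nu) || nu <= -1 || nu >= 0.5) stop("need -1 < nu < 0.5")
  }
  if (model == "mooney_rivlin" && (is.null(bulk) || bulk <= 0))
    stop("Mooney-Rivlin card needs bulk > 0")
  if (model == "linear_spring" && (is.null(E) || E <= 0))
    stop("spring card needs E > 0")
  structure(list(name = name, model = model, E = E, nu = nu, c1 = c1, c2 = c2,
                 bulk = bulk, density = density), class = "material_card")
}

#' Default material cards
#'
#' The lumbar model's constitutive set: cortical bone E = 12000 MPa,
#' nu = 0.3; cancellous bone E = 100 MPa, nu = 0.2; nucleus Mooney--Rivlin
#' c1 = 0.12, c2 = 0.09, bulk = 666.67 MPa; annulus c1 = 0.56, c2 = 0.14,
#' bulk = 14.89 MPa (both density 1.0003 g/cm^3); cartilage E = 23.8 MPa,
#' nu = 0.4; ligaments linear springs with E = 0.22 MPa; the upper endplate
#' of L1 and the lower endplate of L5 rigid.
#'
#' @return named list of [material_card]s.
#' @export
default_materials <- function() {
  list(
    cortical = material_card("cortical", "isotropic_elastic", E = 12000, nu = 0.3),
    cancellous = material_card("cancellous", "isotropic_elastic", E = 100, nu = 0.2),
    nucleus = material_card("nucleus", "mooney_rivlin", c1 = 0.12, c2 = 0.09,
                            bulk = 666.67, density = 1.0003),
    annulus = material_card("annulus", "mooney_rivlin", c1 = 0.56, c2 = 0.14,
                            bulk = 14.89, density = 1.0003),
    cartilage = material_card("cartilage", "isotropic_elastic", E = 23.8,
                              nu = 0.4, density = 1.0003),
    ligament = material_card("ligament", "linear_spring", E = 0.22),
    rigid_L1_upper_endplate = material_card("rigid_L1_upper_endplate", "rigid",
                                            density = 1),
    rigid_L5_lower_endplate = material_card("rigid_L5_lower_endplate", "rigid",
                                            density = 1))
}

#' Load case (forces N, moments N m) applied to the L1 upper-endplate rigid body
#' @param name case name.
#' @param Fx,Fy,Fz forces, N.
#' @param Mx,My,Mz moments, N m.
#' @param application rigid body the loads bind to.
#' @export
load_case <- function(name, Fx = 0, Fy = 0, Fz = 0, Mx = 0, My = 0, Mz = 0,
                      application = "L1_upper_endplate") {
  structure(list(name = name, Fx = Fx, Fy = Fy, Fz = Fz, Mx = Mx, My = My,
                 Mz = Mz, application = application), class = "load_case")
}

#' Default physiological load cases
#'
#' Extension (Mx = -7.5 N m, Fz = -50 N), flexion (Mx = 7.5 N m,
#' Fz = -117.5 N), axial rotation (Mz = 5.5 N m, Fz = -72 N) and lateral
#' bending (My = 7.8 N m, Fz = -70 N), applied to the L1 upper endplate
#' while the L5 lower endplate is fully constrained.
#'
#' @return named list of [load_case]s.
#' @export
default_load_cases <- function() {
  list(extension = load_case("extension", Mx = -7.5, Fz = -50),
       flexion = load_case("flexion", Mx = 7.5, Fz = -117.5),
       axial_rotation = load_case("axial_rotation", Mz = 5.5, Fz = -72),
       lateral_bending = load_case("lateral_bending", My = 7.8, Fz = -70))
}

#' Contact definition between two parts
#' @param kind `"stick"`, `"tied"` or `"node_to_surface"`.
#' @param primary,secondary part names (or part / node-set for
#'   node-to-surface).
#' @param tolerance overlap tolerance, mm (default 0.01).
#' @export
contact_definition <- function(kind, primary, secondary, tolerance = 0.01) {
  kind <- match.arg(kind, c("stick", "tied", "node_to_surface"))
  if (tolerance <= 0) stop("tolerance must be > 0")
  structure(list(kind = kind, primary = primary, secondary = secondary,
                 tolerance = tolerance), class = "contact_definition")
}

# count coincident node coordinates between two parts (within tol)
.count_coincident <- function(A, B, tol = 0.01) {
  ka <- sprintf("%.0f %.0f %.0f", round(A[, 1L] / tol), round(A[, 2L] / tol),
                round(A[, 3L] / tol))
  kb <- sprintf("%.0f %.0f %.0f", round(B[, 1L] / tol), round(B[, 2L] / tol),
                round(B[, 3L] / tol))
  sum(ka %in% kb)
}

#' Assemble the finite-element model
#'
#' Collects all part volumes, assigns material cards, auto-generates the
#' contact set (stick nucleus-annulus per disc, tied cartilage-endplate per
#' interface, node-to-surface per ligament instance), fixes every node of
#' the L5 lower endplate, declares the L1 upper / L5 lower endplate rigid
#' bodies and binds the load cases to the L1 upper endplate.
#'
#' @param bones named list (`L1`..) of `bone_split` results.
#' @param discs named list (`D1`..) of `disc_partition`s.
#' @param cartilage named list of `cartilage_segment`s.
#' @param endplates named list (`L1`..) of [extract_endplates()] results.
#' @param springs named list: segment -> list of `spring_set`s.
#' @param materials named list of [material_card]s.
#' @param loads named list of [load_case]s.
#' @return object of class `fe_model`.
#' @export
assemble_model <- function(bones, discs, cartilage, endplates, springs,
                           materials = default_materials(),
                           loads = default_load_cases()) {
  parts <- list()
  part_materials <- character(0)
  for (lev in names(bones)) {
    parts[[paste0(lev, "_cortical")]] <- bones[[lev]]$cortical_shell
    parts[[paste0(lev, "_cancellous")]] <- bones[[lev]]$cancellous_core
    part_materials[paste0(lev, "_cortical")] <- "cortical"
    part_materials[paste0(lev, "_cancellous")] <- "cancellous"
  }
  for (dk in names(discs)) {
    parts[[paste0(dk, "_nucleus")]] <- discs[[dk]]$nucleus_solid
    parts[[paste0(dk, "_annulus")]] <- discs[[dk]]$annulus_solid
    part_materials[paste0(dk, "_nucleus")] <- "nucleus"
    part_materials[paste0(dk, "_annulus")] <- "annulus"
  }
  for (lab in names(cartilage)) {
    parts[[lab]] <- cartilage[[lab]]$solid
    part_materials[lab] <- "cartilage"
  }
  missing_mat <- setdiff(unique(part_materials), names(materials))
  if (length(missing_mat) > 0L)
    stop("missing material card(s): ", paste(missing_mat, collapse = ", "),
         " (first part affected: ",
         names(part_materials)[part_materials %in% missing_mat][1L], ")")
  # contacts
  contacts <- list()
  for (dk in names(discs))
    contacts[[paste0("stick_", dk)]] <-
      contact_definition("stick", paste0(dk, "_nucleus"), paste0(dk, "_annulus"))
  nd <- length(discs)
  for (k in seq_len(nd)) {
    for (side in 1:2) {
      lev <- if (side == 1L) k else k + 1L
      lab <- sprintf("L%dD%d", lev, k)
      if (!lab %in% names(cartilage)) next
      contacts[[paste0("tied_", lab)]] <-
        contact_definition("tied", lab, sprintf("L%d_cortical", lev))
    }
  }
  # springs: flatten, validate endpoints, one node-to-surface per instance
  flat_springs <- list()
  for (seg in names(springs)) {
    for (lg in names(springs[[seg]])) {
      ss <- springs[[seg]][[lg]]
      nm <- paste0(seg, "_", lg)
      ep <- ss$endpoints
      for (side in c("upper", "lower")) {
        pn <- ep[[paste0("part_", side)]][1L]
        if (!pn %in% names(parts))
          stop("dangling spring endpoint: part '", pn, "' in ", nm)
        nn <- nrow(parts[[pn]]$vertices)
        bad <- ep[[paste0("node_", side)]] > nn
        if (any(bad))
          stop("dangling spring endpoint node in ", nm, " (part ", pn, ")")
      }
      flat_springs[[nm]] <- ss
      contacts[[paste0("n2s_", nm)]] <-
        contact_definition("node_to_surface", ep$part_lower[1L], nm)
    }
  }
  # boundary: all nodes of the L5 lower endplate (cortical outer layer keeps
  # the surface vertex indexing, so patch indices are valid node ids)
  last <- names(bones)[length(bones)]
  first <- names(bones)[1L]
  fixed <- list()
  fixed[[paste0(last, "_cortical")]] <-
    endplates[[last]]$lower$vertex_indices
  rigid_bodies <- list(
    L1_upper_endplate = list(part = paste0(first, "_cortical"),
                             nodes = endplates[[first]]$upper$vertex_indices,
                             material = "rigid_L1_upper_endplate"),
    L5_lower_endplate = list(part = paste0(last, "_cortical"),
                             nodes = endplates[[last]]$lower$vertex_indices,
                             material = "rigid_L5_lower_endplate"))
  # coincident-node report across declared contact interfaces
  coincident <- vapply(contacts, function(ct) {
    if (ct$kind == "node_to_surface") return(NA_real_)
    a <- parts[[ct$primary]]
    b <- parts[[ct$secondary]]
    if (is.null(a) || is.null(b)) return(NA_real_)
    .count_coincident(a$vertices, b$vertices, ct$tolerance)
  }, 0)
  structure(list(parts = parts, part_materials = part_materials,
                 materials = materials, springs = flat_springs,
                 contacts = contacts, fixed = fixed,
                 rigid_bodies = rigid_bodies, loads = loads,
                 coincident_nodes = coincident),
            class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  ns <- sum(vapply(x$springs, function(s) nrow(s$endpoints), 0L))
  kinds <- table(vapply(x$contacts, `[[`, "", "kind"))
  cat(sprintf("fe_model: %d parts, %d springs, contacts [%s], %d load cases\n",
              length(x$parts), ns,
              paste(names(kinds), kinds, sep = "=", collapse = ", "),
              length(x$loads)))
  invisible(x)
}

#' Total spring count of a model
#' @param model an `fe_model`.
#' @export
n_springs <- function(model)
  sum(vapply(model$springs, function(s) nrow(s$endpoints), 0L))
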