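#' Export a model as FEBio-format XML (spec 2.5)
#'
#' Writes Globals, Material (isotropic elastic / Mooney-Rivlin / rigid
#' body), Geometry (per-part Nodes and tet4 Elements with contiguous global
#' ids, NodeSets, contact Surfaces and SurfacePairs, per-spring
#' DiscreteSets), Boundary (fixed L5 lower endplate, rigid-body node sets),
#' Contact (sticky / tied-node-on-facet / sliding-node-on-facet), Discrete
#' (one linear-spring material per spring, stiffness k = E A / L with the
#' effective area `spring_area`), and one quasi-static Step per load case
#' with `n_increments` equal load increments. Node coordinates carry 12
#' significant digits so a write/read cycle preserves them to better than
#' 1e-9 relative.
#'
#' @param model an `fe_model`.
#' @param path output file path.
#' @param spring_area effective ligament cross-section per spring, mm^2.
#' @param n_increments quasi-static load increments per step.
#' @return `path`, invisibly.
#' @export
export_feb <- function(model, path, spring_area = 10, n_increments = 10L) {
  mats <- model$materials
  mat_id <- stats::setNames(seq_along(mats), names(mats))
  L <- character(0)
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  addv <- function(v) L[[length(L) + 1L]] <<- paste(v, collapse = "\n")
  add('<?xml version="1.0" encoding="ISO-8859-1"?>')
  add('<febio_spec version="2.5">')
  add('  <Module type="solid"/>')
  add('  <Globals><Constants><T>0</T><R>0</R><Fc>0</Fc></Constants></Globals>')
  add('  <Material>')
  for (i in seq_along(mats)) {
    m <- mats[[i]]
    if (m$model == "isotropic_elastic") {
      add(sprintf('    <material id="%d" name="%s" type="isotropic elastic">', i, m$name))
      add(sprintf('      <E>%.9g</E><v>%.9g</v>', m$E, m$nu))
      if (!is.null(m$density)) add(sprintf('      <density>%.9g</density>', m$density))
      add('    </material>')
    } else if (m$model == "mooney_rivlin") {
      add(sprintf('    <material id="%d" name="%s" type="Mooney-Rivlin">', i, m$name))
      add(sprintf('      <c1>%.9g</c1><c2>%.9g</c2><k>%.9g</k>', m$c1, m$c2, m$bulk))
      if (!is.null(m$density)) add(sprintf('      <density>%.9g</density>', m$density))
      add('    </material>')
    } else if (m$model == "rigid") {
      add(sprintf('    <material id="%d" name="%s" type="rigid body">', i, m$name))
      add(sprintf('      <density>%.9g</density>', m$density %||% 1))
      add('      <center_of_mass>0,0,0</center_of_mass>')
      add('    </material>')
    }
    # linear_spring cards are realized in the Discrete section
  }
  add('  </Material>')
  # ---- geometry ----
  offs <- integer(0)
  off <- 0L
  for (pn in names(model$parts)) {
    offs[pn] <- off
    off <- off + nrow(model$parts[[pn]]$vertices)
  }
  add('  <Geometry>')
  for (pn in names(model$parts)) {
    tm <- model$parts[[pn]]
    V <- tm$vertices
    ids <- offs[pn] + seq_len(nrow(V))
    add(sprintf('    <Nodes name="%s">', pn))
    addv(sprintf('      <node id="%d">%.12g,%.12g,%.12g</node>', ids,
                 V[, 1L], V[, 2L], V[, 3L]))
    add('    </Nodes>')
  }
  el_id <- 0L
  for (pn in names(model$parts)) {
    tm <- model$parts[[pn]]
    C <- tm$cells + offs[pn]
    mid <- mat_id[[model$part_materials[[pn]]]]
    add(sprintf('    <Elements type="tet4" mat="%d" name="%s">', mid, pn))
    addv(sprintf('      <elem id="%d">%d,%d,%d,%d</elem>',
                 el_id + seq_len(nrow(C)), C[, 1L], C[, 2L], C[, 3L], C[, 4L]))
    el_id <- el_id + nrow(C)
    add('    </Elements>')
  }
  for (fn in names(model$fixed)) {
    ids <- offs[fn] + model$fixed[[fn]]
    add(sprintf('    <NodeSet name="fixed_%s">', fn))
    addv(sprintf('      <node id="%d"/>', ids))
    add('    </NodeSet>')
  }
  for (rn in names(model$rigid_bodies)) {
    rb <- model$rigid_bodies[[rn]]
    ids <- offs[rb$part] + rb$nodes
    add(sprintf('    <NodeSet name="%s">', rn))
    addv(sprintf('      <node id="%d"/>', ids))
    add('    </NodeSet>')
  }
  # contact surfaces (part boundary faces) for stick/tied pairs
  surf_written <- character(0)
  tri_id <- 0L
  for (cn in names(model$contacts)) {
    ct <- model$contacts[[cn]]
    if (ct$kind == "node_to_surface") next
    for (pn in c(ct$primary, ct$secondary)) {
      if (pn %in% surf_written) next
      surf_written <- c(surf_written, pn)
      B <- model$parts[[pn]]$boundary_faces + offs[pn]
      add(sprintf('    <Surface name="surf_%s">', pn))
      addv(sprintf('      <tri3 id="%d">%d,%d,%d</tri3>',
                   tri_id + seq_len(nrow(B)), B[, 1L], B[, 2L], B[, 3L]))
      tri_id <- tri_id + nrow(B)
      add('    </Surface>')
    }
    add(sprintf('    <SurfacePair name="%s">', cn))
    add(sprintf('      <primary surface="surf_%s"/>', ct$primary))
    add(sprintf('      <secondary surface="surf_%s"/>', ct$secondary))
    add('    </SurfacePair>')
  }
  # node-to-surface: one node set per ligament instance
  for (cn in names(model$contacts)) {
    ct <- model$contacts[[cn]]
    if (ct$kind != "node_to_surface") next
    ss <- model$springs[[ct$secondary]]
    ep <- ss$endpoints
    ids <- c(offs[ep$part_upper[1L]] + ep$node_upper,
             offs[ep$part_lower[1L]] + ep$node_lower)
    add(sprintf('    <NodeSet name="ns_%s">', ct$secondary))
    addv(sprintf('      <node id="%d"/>', sort(unique(ids))))
    add('    </NodeSet>')
  }
  # one discrete set per spring
  k_spring <- 0L
  for (sn in names(model$springs)) {
    ep <- model$springs[[sn]]$endpoints
    for (i in seq_len(nrow(ep))) {
      k_spring <- k_spring + 1L
      add(sprintf('    <DiscreteSet name="spring_%d">', k_spring))
      add(sprintf('      <delem>%d,%d</delem>',
                  offs[ep$part_upper[i]] + ep$node_upper[i],
                  offs[ep$part_lower[i]] + ep$node_lower[i]))
      add('    </DiscreteSet>')
    }
  }
  add('  </Geometry>')
  # ---- boundary ----
  add('  <Boundary>')
  for (fn in names(model$fixed))
    add(sprintf('    <fix bc="x,y,z" node_set="fixed_%s"/>', fn))
  for (rn in names(model$rigid_bodies)) {
    rb <- model$rigid_bodies[[rn]]
    add(sprintf('    <rigid node_set="%s" rb="%d"/>', rn, mat_id[[rb$material]]))
  }
  add('  </Boundary>')
  # ---- contact ----
  feb_type <- c(stick = "sticky", tied = "tied-node-on-facet",
                node_to_surface = "sliding-node-on-facet")
  add('  <Contact>')
  for (cn in names(model$contacts)) {
    ct <- model$contacts[[cn]]
    if (ct$kind == "node_to_surface") {
      add(sprintf('    <contact type="%s" name="%s" node_set="ns_%s" surface="surf_%s_bd">',
                  feb_type[[ct$kind]], cn, ct$secondary, ct$primary))
    } else {
      add(sprintf('    <contact type="%s" name="%s" surface_pair="%s">',
                  feb_type[[ct$kind]], cn, cn))
    }
    add(sprintf('      <tolerance>%.9g</tolerance>', ct$tolerance))
    add('    </contact>')
  }
  add('  </Contact>')
  # ---- discrete springs ----
  add('  <Discrete>')
  lig <- model$materials$ligament
  E_lig <- if (!is.null(lig)) lig$E else 0.22
  k_spring <- 0L
  for (sn in names(model$springs)) {
    ep <- model$springs[[sn]]$endpoints
    for (i in seq_len(nrow(ep))) {
      k_spring <- k_spring + 1L
      kval <- E_lig * spring_area / ep$rest_length[i]
      add(sprintf('    <discrete_material id="%d" name="%s_%d" type="linear spring">',
                  k_spring, sn, i))
      add(sprintf('      <E>%.9g</E>', kval))
      add('    </discrete_material>')
      add(sprintf('    <discrete dmat="%d" discrete_set="spring_%d"/>',
                  k_spring, k_spring))
    }
  }
  add('  </Discrete>')
  add('  <LoadData>')
  add('    <loadcurve id="1" type="linear"><point>0,0</point><point>1,1</point></loadcurve>')
  add('  </LoadData>')
  # ---- steps: one quasi-static step per load case ----
  for (lc in model$loads) {
    rbmat <- mat_id[[model$rigid_bodies[[lc$application]]$material]]
    add(sprintf('  <Step name="%s">', lc$name))
    add('    <Control>')
    add(sprintf('      <time_steps>%d</time_steps>', as.integer(n_increments)))
    add(sprintf('      <step_size>%.9g</step_size>', 1 / n_increments))
    add('      <analysis type="static"/>')
    add('    </Control>')
    add('    <Loads>')
    add(sprintf('      <rigid_body mat="%d">', rbmat))
    comp <- c(Fx = "x", Fy = "y", Fz = "z")
    for (f in names(comp))
      if (lc[[f]] != 0)
        add(sprintf('        <force bc="%s" lc="1">%.9g</force>', comp[[f]], lc[[f]]))
    mcomp <- c(Mx = "Rx", My = "Ry", Mz = "Rz")
    for (f in names(mcomp))
      if (lc[[f]] != 0)
        add(sprintf('        <moment bc="%s" lc="1">%.9g</moment>', mcomp[[f]], lc[[f]]))
    add('      </rigid_body>')
    add('    </Loads>')
    add('  </Step>')
  }
  add('</febio_spec>')
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(unlist(L), con)
  invisible(path)
}

#' Re-parse an exported FEBio file
#'
#' Reads back part names, node coordinates, element connectivity, spring,
#' contact and step counts for round-trip verification.
#'
#' @param path a `.feb` file written by [export_feb()].
#' @return list with `parts` (per part: `vertices`, `cells`), `n_springs`,
#'   `n_contacts`, `n_steps`, `n_materials`, `node_sets`.
#' @export
read_feb <- function(path) {
  doc <- xml2::read_xml(path)
  parts <- list()
  for (nd in xml2::xml_find_all(doc, ".//Geometry/Nodes")) {
    nm <- xml2::xml_attr(nd, "name")
    txt <- xml2::xml_text(xml2::xml_find_all(nd, "node"))
    V <- matrix(as.numeric(unlist(strsplit(txt, ","))), ncol = 3L, byrow = TRUE)
    ids <- as.integer(xml2::xml_attr(xml2::xml_find_all(nd, "node"), "id"))
    parts[[nm]] <- list(vertices = V, node_ids = ids)
  }
  for (el in xml2::xml_find_all(doc, ".//Geometry/Elements")) {
    nm <- xml2::xml_attr(el, "name")
    txt <- xml2::xml_text(xml2::xml_find_all(el, "elem"))
    C <- matrix(as.integer(unlist(strsplit(txt, ","))), ncol = 4L, byrow = TRUE)
    # back to part-local 1-based indexing
    parts[[nm]]$cells <- C - min(parts[[nm]]$node_ids) + 1L
    parts[[nm]]$mat <- as.integer(xml2::xml_attr(el, "mat"))
  }
  node_sets <- lapply(xml2::xml_find_all(doc, ".//Geometry/NodeSet"), function(ns)
    as.integer(xml2::xml_attr(xml2::xml_find_all(ns, "node"), "id")))
  names(node_sets) <- xml2::xml_attr(xml2::xml_find_all(doc, ".//Geometry/NodeSet"), "name")
  list(parts = parts,
       n_springs = length(xml2::xml_find_all(doc, ".//Discrete/discrete")),
       n_contacts = length(xml2::xml_find_all(doc, ".//Contact/contact")),
       n_steps = length(xml2::xml_find_all(doc, "./Step")),
       n_materials = length(xml2::xml_find_all(doc, ".//Material/material")),
       node_sets = node_sets)
}
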