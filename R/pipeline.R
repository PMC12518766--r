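#' Build a complete lumbar-spine FE model from labeled meshes
#'
#' Runs the whole preprocessing chain on a labeled map of vertebra
#' (`L1`..`Ln`) and disc (`D1`..`D(n-1)`) surface meshes: cortical/
#' cancellous split per vertebra, nucleus/annulus separation per disc,
#' endplate extraction, ligament spring generation over every motion
#' segment, cartilage at each vertebra-disc interface, and model assembly
#' with the default material cards and load cases.
#'
#' @param stack named list of closed [trimesh]es (e.g. from
#'   [make_lumbar_stack()] or [read_spine_dir()]).
#' @param bone_params a [bone_split_params].
#' @param disc_scale nucleus scale factor.
#' @param point_spacing disc surface/grid spacing, mm.
#' @param endplate_parameters an [endplate_params].
#' @param ligament_table from [default_ligament_table()].
#' @param max_gap cartilage contact threshold, mm.
#' @param materials,loads material cards and load cases.
#' @param verbose print stage progress.
#' @return list of class `spine_pipeline`: `model` (the `fe_model`) plus
#'   all intermediates (`bones`, `discs`, `endplates`, `springs`,
#'   `cartilage`).
#' @export
build_spine_model <- function(stack,
                              bone_params = bone_split_params(),
                              disc_scale = 0.6,
                              point_spacing = 1,
                              endplate_parameters = endplate_params(),
                              ligament_table = default_ligament_table(),
                              max_gap = 2,
                              materials = default_materials(),
                              loads = default_load_cases(),
                              verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  levels <- grep("^L\\d+$", names(stack), value = TRUE)
  dlevels <- grep("^D\\d+$", names(stack), value = TRUE)
  levels <- levels[order(as.integer(sub("L", "", levels)))]
  dlevels <- dlevels[order(as.integer(sub("D", "", dlevels)))]
  if (length(levels) < 2L || length(dlevels) != length(levels) - 1L)
    stop("stack must hold L1..Ln and D1..D(n-1) meshes")
  bones <- list()
  for (lev in levels) {
    say("splitting %s into cortical shell and cancellous core", lev)
    bones[[lev]] <- split_vertebra(stack[[lev]], bone_params)
  }
  discs <- list()
  for (dk in dlevels) {
    say("separating %s into nucleus and annulus", dk)
    discs[[dk]] <- split_disc(stack[[dk]], scale = disc_scale,
                              point_spacing = point_spacing)
  }
  endplates <- list()
  for (lev in levels) {
    say("extracting endplates of %s", lev)
    endplates[[lev]] <- extract_endplates(bones[[lev]]$cortical_outer,
                                          endplate_parameters)
  }
  springs <- list()
  for (k in seq_len(length(levels) - 1L)) {
    up <- levels[k]
    lo <- levels[k + 1L]
    say("ligaments for motion segment %s-%s", up, lo)
    springs[[paste0(up, lo)]] <-
      segment_ligaments(bones[[up]]$cortical_outer, bones[[lo]]$cortical_outer,
                        parts = c(paste0(up, "_cortical"), paste0(lo, "_cortical")),
                        table = ligament_table)
  }
  say("building cartilage segments")
  cartilage <- build_all_cartilage(endplates, discs, max_gap)
  say("assembling the model")
  model <- assemble_model(bones, discs, cartilage, endplates, springs,
                          materials, loads)
  structure(list(model = model, bones = bones, discs = discs,
                 endplates = endplates, springs = springs,
                 cartilage = cartilage, stack = stack),
            class = "spine_pipeline")
}

#' @export
print.spine_pipeline <- function(x, ...) {
  cat("spine_pipeline with", length(x$bones), "vertebrae and",
      length(x$discs), "discs\n")
  print(x$model)
  invisible(x)
}

#' Read a directory of labeled spine meshes
#'
#' Loads `L1.stl` .. `Ln.stl` and `D1.stl` .. `D(n-1).stl` (or `.vtk` /
#' `.obj`) from a directory into a labeled stack.
#'
#' @param dir directory path.
#' @return named list of [trimesh]es.
#' @export
read_spine_dir <- function(dir) {
  files <- list.files(dir, pattern = "^[LD]\\d+\\.(stl|vtk|obj)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L) stop("no labeled meshes (L*.stl / D*.stl) in ", dir)
  out <- list()
  for (f in files)
    out[[toupper(tools::file_path_sans_ext(basename(f)))]] <- read_mesh(f)
  out
}

#' Write a synthetic stack to STL files plus a JSON manifest
#'
#' @param params a [spine_params].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_synthetic_spine <- function(params, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stack <- make_lumbar_stack(params)
  for (nm in names(stack)) write_stl(stack[[nm]], file.path(dir, paste0(nm, ".stl")))
  jsonlite::write_json(unclass(params), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
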