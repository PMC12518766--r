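test_that("default material cards carry the published constitutive values", {
  mats <- default_materials()
  expect_equal(mats$cortical$E, 12000)
  expect_equal(mats$cortical$nu, 0.3)
  expect_equal(mats$cancellous$E, 100)
  expect_equal(mats$cancellous$nu, 0.2)
  expect_equal(mats$nucleus[c("c1", "c2", "bulk")],
               list(c1 = 0.12, c2 = 0.09, bulk = 666.67))
  expect_equal(mats$annulus[c("c1", "c2", "bulk")],
               list(c1 = 0.56, c2 = 0.14, bulk = 14.89))
  expect_equal(mats$nucleus$density, 1.0003)
  expect_equal(mats$cartilage$E, 23.8)
  expect_equal(mats$cartilage$nu, 0.4)
  expect_equal(mats$ligament$E, 0.22)
  expect_equal(mats$ligament$model, "linear_spring")
  expect_equal(mats$rigid_L1_upper_endplate$model, "rigid")
  expect_equal(mats$rigid_L5_lower_endplate$model, "rigid")
  expect_error(material_card("x", "isotropic_elastic", E = -1, nu = 0.3), "E")
  expect_error(material_card("x", "isotropic_elastic", E = 10, nu = 0.7), "nu")
  expect_error(material_card("x", "mooney_rivlin", c1 = 1, c2 = 1, bulk = 0),
               "bulk")
})

test_that("default load cases are the four physiological scenarios", {
  lc <- default_load_cases()
  expect_setequal(names(lc), c("extension", "flexion", "axial_rotation",
                               "lateral_bending"))
  expect_equal(lc$extension$Mx, -7.5)
  expect_equal(lc$extension$Fz, -50)
  expect_equal(lc$flexion$Mx, 7.5)
  expect_equal(lc$flexion$Fz, -117.5)
  expect_equal(lc$axial_rotation$Mz, 5.5)
  expect_equal(lc$axial_rotation$Fz, -72)
  expect_equal(lc$lateral_bending$My, 7.8)
  expect_equal(lc$lateral_bending$Fz, -70)
  # all other components zero, all applied at the L1 upper endplate
  for (l in lc) {
    others <- setdiff(c("Fx", "Fy", "Fz", "Mx", "My", "Mz"),
                      names(which(unlist(l[c("Fx", "Fy", "Fz", "Mx", "My",
                                             "Mz")]) != 0)))
    expect_true(all(unlist(l[others]) == 0))
    expect_equal(l$application, "L1_upper_endplate")
  }
})

test_that("the assembled model has the full structural inventory", {
  pl <- full_pipeline()
  m <- pl$model
  expect_length(m$parts, 26L)
  expect_setequal(grep("_cortical$", names(m$parts), value = TRUE),
                  paste0("L", 1:5, "_cortical"))
  expect_setequal(grep("_nucleus$", names(m$parts), value = TRUE),
                  paste0("D", 1:4, "_nucleus"))
  expect_equal(n_springs(m), 10L * 8L * 4L)
  kinds <- table(vapply(m$contacts, `[[`, "", "kind"))
  expect_equal(kinds[["stick"]], 4L)
  expect_equal(kinds[["tied"]], 8L)
  expect_equal(kinds[["node_to_surface"]], length(m$springs))
  # fixed node set: non-empty, only on the L5 cortical part, equals the
  # lower endplate patch
  expect_equal(names(m$fixed), "L5_cortical")
  expect_gt(length(m$fixed$L5_cortical), 0)
  expect_setequal(m$fixed$L5_cortical, pl$endplates$L5$lower$vertex_indices)
  # materials byte-identical to the defaults; loads bound to L1 upper
  expect_identical(m$materials, default_materials())
  expect_identical(m$loads, default_load_cases())
  expect_equal(m$rigid_bodies$L1_upper_endplate$part, "L1_cortical")
})

test_that("assembly validates materials and spring endpoints", {
  pl <- full_pipeline()
  mats <- default_materials()
  mats$cartilage <- NULL
  expect_error(assemble_model(pl$bones, pl$discs, pl$cartilage, pl$endplates,
                              pl$springs, materials = mats), "cartilage")
  bad <- pl$springs
  bad$L1L2$ALL$endpoints$node_upper[1] <- 10^7
  expect_error(assemble_model(pl$bones, pl$discs, pl$cartilage, pl$endplates,
                              bad), "dangling")
})

test_that("FEB export re-parses with identical counts and coordinates", {
  pl <- full_pipeline()
  m <- pl$model
  path <- file.path(tempdir(), "model.feb")
  export_feb(m, path)
  fb <- read_feb(path)
  expect_setequal(names(fb$parts), names(m$parts))
  for (pn in names(m$parts)) {
    expect_equal(nrow(fb$parts[[pn]]$vertices), nrow(m$parts[[pn]]$vertices))
    expect_equal(nrow(fb$parts[[pn]]$cells), nrow(m$parts[[pn]]$cells))
    rel <- abs(fb$parts[[pn]]$vertices - m$parts[[pn]]$vertices) /
      pmax(abs(m$parts[[pn]]$vertices), 1)
    expect_lt(max(rel), 1e-9)
  }
  expect_equal(fb$n_springs, n_springs(m))
  expect_equal(fb$n_contacts, length(m$contacts))
  expect_equal(fb$n_steps, length(m$loads))
  # fixed node set present and within the L5 cortical global id range
  expect_true("fixed_L5_cortical" %in% names(fb$node_sets))
  expect_equal(length(fb$node_sets$fixed_L5_cortical),
               length(m$fixed$L5_cortical))
})

test_that("VTK export preserves cells, coordinates and spring counts", {
  pl <- full_pipeline()
  m <- pl$model
  dir <- file.path(tempdir(), "vtk_out")
  export_vtk(m, dir)
  for (pn in c("L3_cortical", "D2_nucleus", "L2D2")) {
    got <- read_vtk_unstructured(file.path(dir, paste0(pn, ".vtk")))
    expect_equal(nrow(got$cells), nrow(m$parts[[pn]]$cells))
    rel <- abs(got$vertices - m$parts[[pn]]$vertices) /
      pmax(abs(m$parts[[pn]]$vertices), 1)
    expect_lt(max(rel), 1e-9)
    expect_equal(length(unique(got$labels)), 1L)
  }
  sp <- read_vtk_springs(file.path(dir, "springs.vtk"))
  expect_equal(sp$n_lines, n_springs(m))
})
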