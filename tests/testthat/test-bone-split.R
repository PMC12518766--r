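test_that("inward offset recovers the analytic offset sphere and cube corners", {
  s <- icosphere(4, 10)
  core <- offset_inward(s, 0.3)
  r <- sqrt(rowSums(core$vertices^2))
  expect_true(all(abs(r - 9.7) < 0.05))
  expect_identical(core$faces, s$faces)
  # identity at zero thickness
  expect_identical(offset_inward(s, 0)$vertices, s$vertices)
  # cube corners move along the corner diagonal (normalized sum of 3 face
  # normals) by the full thickness
  cb <- cube_mesh()
  oc <- offset_inward(cb, 0.1)
  shift <- oc$vertices - cb$vertices
  len <- sqrt(rowSums(shift^2))
  expect_true(all(abs(len - 0.1) < 1e-9))
  dir0 <- shift[1, ] / len[1]   # corner (0,0,0): inward diagonal
  expect_equal(dir0, rep(1 / sqrt(3), 3), tolerance = 1e-9)
  expect_error(offset_inward(trimesh(s$vertices, s$faces[-1, ], clean = FALSE),
                             0.3), "open")
})

test_that("cancellous extraction smooths within the documented radius band", {
  s <- icosphere(5, 10)
  core <- extract_cancellous(s, bone_split_params())
  expect_true(is_closed(core))
  expect_equal(nrow(self_intersections(core)), 0L)
  r <- mean(sqrt(rowSums(core$vertices^2)))
  expect_gt(r, 9.55)
  expect_lt(r, 9.75)
  # vanishing smoothing converges to the raw offset
  tiny <- extract_cancellous(s, bone_split_params(
    smoothing = smoothing_params(1e-6, 1L)))
  raw <- offset_inward(s, 0.3)
  expect_lt(max(abs(tiny$vertices - raw$vertices)), 1e-4)
})

test_that("cortical shell matches the analytic concentric-sphere volume and
           conserves the total", {
  s <- icosphere(4, 10)
  core <- offset_inward(s, 0.3)
  vols <- build_cortical_shell(s, core)
  analytic <- 4 / 3 * pi * (10^3 - 9.7^3)
  expect_lt(abs(tet_volume(vols$cortical_shell) - analytic) / analytic, 0.03)
  vo <- enclosed_volume(s)
  expect_lt(abs(tet_volume(vols$cortical_shell) +
                  tet_volume(vols$cancellous_core) - vo) / vo, 0.02)
  # interface nodes shared with identical coordinates
  core_surface_keys <- apply(core$vertices, 1, paste, collapse = " ")
  shell_keys <- apply(vols$cortical_shell$vertices, 1, paste, collapse = " ")
  expect_true(all(core_surface_keys %in% shell_keys))
  # containment violation reported with vertex indices
  inflated <- core
  inflated$vertices <- inflated$vertices * 1.2
  expect_error(build_cortical_shell(s, inflated), "outside")
})

test_that("full vertebra split conserves volume and shrinks with thickness", {
  p <- spine_params(seed = 5, mesh_subdiv = 3)
  v <- make_vertebra(p, 2)
  bs1 <- split_vertebra(v, bone_split_params(t_core = 0.3))
  vo <- enclosed_volume(bs1$cortical_outer)
  expect_lt(abs(tet_volume(bs1$cortical_shell) +
                  tet_volume(bs1$cancellous_core) - vo) / vo, 0.02)
  expect_lt(tet_volume(bs1$cancellous_core), vo)
  # monotonicity: thicker cortex => smaller cancellous core
  bs2 <- split_vertebra(v, bone_split_params(t_core = 0.6))
  expect_lt(tet_volume(bs2$cancellous_core), tet_volume(bs1$cancellous_core))
})

test_that("bone split commutes with arbitrary rigid motions", {
  s <- icosphere(3, 10)
  set.seed(31)
  R <- random_rotation()
  tr <- c(12, -7, 30)
  params <- bone_split_params()
  a <- extract_cancellous(s, params)
  b <- extract_cancellous(translate_mesh(rotate_mesh(s, R), tr), params)
  moved <- sweep(a$vertices %*% t(R), 2, tr, "+")
  expect_lt(max(abs(moved - b$vertices)), 1e-6)
})
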