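test_that("generated vertebrae are closed, deterministic and volume-plausible", {
  p <- spine_params(seed = 42)
  v1 <- make_vertebra(p, 1)
  expect_true(is_closed(v1))
  expect_equal(nrow(self_intersections(v1)), 0L)
  v1b <- make_vertebra(p, 1)
  expect_identical(v1$vertices, v1b$vertices)
  expect_identical(v1$faces, v1b$faces)
  expect_error(make_vertebra(p, 0), "level")
  expect_error(make_vertebra(p, 6), "level")
  # noise-free volume against an independent radial-quadrature oracle
  p0 <- spine_params(seed = 1, noise_amplitude = 0)
  v0 <- make_vertebra(p0, 3)
  oracle <- radial_volume_oracle(function(U) spineforge:::.vertebra_radius(U, p0))
  expect_lt(abs(enclosed_volume(translate_mesh(v0, -centroid(v0))) - oracle) /
              oracle, 0.05)
})

test_that("generated discs are transverse-plane oriented and sit between levels", {
  p <- spine_params(seed = 42)
  d1 <- make_disc(p, 1)
  expect_true(is_closed(d1))
  fr <- pca_frame(d1$vertices)
  ang <- acos(abs(sum(fr$axes[, 3] * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 2)
  z1 <- level_height(p, 1)
  z2 <- level_height(p, 2)
  expect_true(all(d1$vertices[, 3] < z1 & d1$vertices[, 3] > z2))
  # geometry-only determinism: the seed perturbs only the noise field
  pa <- spine_params(seed = 1, noise_amplitude = 0)
  pb <- spine_params(seed = 99, noise_amplitude = 0)
  expect_identical(make_disc(pa, 2)$vertices, make_disc(pb, 2)$vertices)
  expect_error(make_disc(p, 5), "level")
})

test_that("the lumbar stack is labeled, ordered and mutually clear", {
  p <- spine_params(seed = 1)
  stack <- default_stack()
  expect_setequal(names(stack), c(paste0("L", 1:5), paste0("D", 1:4)))
  zc <- vapply(paste0("L", 1:5), function(k) centroid(stack[[k]])[3], 0)
  expect_true(all(diff(zc) < 0))  # L5 inferior
  # pairwise clearance >= gap / 2 (vertex clouds; facet sag << gap/2)
  nms <- names(stack)
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (j <= i) next
    d <- spineforge:::cpp_min_point_dist(stack[[nms[i]]]$vertices,
                                         stack[[nms[j]]]$vertices, 5)
    expect_gte(d, p$gap / 2)
  }
  # reduced stack count
  st2 <- make_lumbar_stack(spine_params(n_levels = 2, seed = 3, mesh_subdiv = 3))
  expect_setequal(names(st2), c("L1", "L2", "D1"))
  # determinism of the whole map
  st3 <- make_lumbar_stack(spine_params(n_levels = 2, seed = 3, mesh_subdiv = 3))
  expect_identical(st2, st3)
})
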