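test_that("spherical-to-Cartesian conversion matches direct trigonometry", {
  expect_equal(spherical_to_cartesian(spherical_coordinate(0, 123, 1)),
               c(0, 0, 1), tolerance = 1e-12)
  expect_equal(spherical_to_cartesian(spherical_coordinate(90, 0, 2)),
               c(2, 0, 0), tolerance = 1e-12)
  # published anterior-longitudinal lower attachment, independent evaluation
  got <- spherical_to_cartesian(spherical_coordinate(29.063, -85, 18))
  p <- 29.063 * pi / 180
  t <- -85 * pi / 180
  expect_equal(got, 18 * c(sin(p) * cos(t), sin(p) * sin(t), cos(p)),
               tolerance = 1e-12)
  expect_equal(got, c(0.762, -8.711, 15.733), tolerance = 1e-3)
})

test_that("half-space selection is the strict dot-product rule", {
  cb <- cube_mesh()
  cb <- translate_mesh(cb, c(-0.5, -0.5, -0.5))
  sel <- select_attachment_vertices(cb, attachment_plane(c(0, 0, 0), c(0, 0, 1)))
  expect_setequal(sel, which(cb$vertices[, 3] > 0))
  expect_length(sel, 4L)
  expect_warning(
    sel2 <- select_attachment_vertices(cb, attachment_plane(c(0, 0, 2), c(0, 0, 1))),
    "empty")
  expect_length(sel2, 0L)
  expect_error(attachment_plane(c(0, 0, 0), c(0, 0, 0)), "zero")
  # exhaustive brute-force agreement on random planes
  set.seed(17)
  P <- matrix(stats::rnorm(600), ncol = 3)
  pm <- trimesh(P, cbind(1:200, c(2:200, 1), c(3:200, 1, 2)), clean = FALSE)
  for (k in 1:20) {
    O <- stats::rnorm(3)
    N <- stats::rnorm(3)
    sel <- select_attachment_vertices(pm, attachment_plane(O, N))
    brute <- which(as.vector((sweep(P, 2, O) %*% N)) > 0)
    expect_identical(sel, brute)
  }
})

test_that("negative r selects the complementary half-space", {
  v <- make_vertebra(spine_params(seed = 6, mesh_subdiv = 3), 1)
  cen <- centroid(v)
  pos <- attachment_region(v, cen, spherical_coordinate(0, 0, 1))
  neg <- attachment_region(v, cen, spherical_coordinate(0, 0, -1))
  expect_length(intersect(pos, neg), 0L)
  offplane <- abs(sweep(v$vertices, 2, cen)[, 3]) > 1e-12
  expect_setequal(c(pos, neg), which(offplane))
  # the supraspinal plane picks a posterior region on the synthetic vertebra
  ssl <- attachment_region(v, cen, spherical_coordinate(25, 90.7, -30))
  expect_gt(length(ssl), 0)
  expect_lt(mean(v$vertices[ssl, 2]), cen[2])
})

test_that("spring generation spreads anchors and pairs nearest vertices", {
  # two parallel congruent grids 5 mm apart
  g <- as.matrix(expand.grid(x = seq(0, 9), y = seq(0, 9)))
  up <- cbind(g, 5)
  lo <- cbind(g, 0)
  mku <- trimesh(up, cbind(1:100, c(2:100, 1), c(3:100, 1, 2)), clean = FALSE)
  mkl <- trimesh(lo, cbind(1:100, c(2:100, 1), c(3:100, 1, 2)), clean = FALSE)
  ss <- build_ligament_springs(mku, 1:100, mkl, 1:100, 10L, "test")
  expect_equal(nrow(ss$endpoints), 10L)
  expect_true(all(abs(ss$endpoints$rest_length - 5) < 0.1))
  # n = 1: centroid-nearest pair
  s1 <- build_ligament_springs(mku, 1:100, mkl, 1:100, 1L, "t1")
  cen <- colMeans(up)
  seed_idx <- which.min(rowSums(sweep(up, 2, cen)^2))
  expect_equal(s1$endpoints$node_upper, seed_idx)
  # single lower vertex: all springs share it
  s2 <- build_ligament_springs(mku, 1:100, mkl, 42L, 10L, "t2")
  expect_true(all(s2$endpoints$node_lower == 42L))
  expect_error(build_ligament_springs(mku, integer(0), mkl, 1:100, 10L, "bad"),
               "empty")
})

test_that("closest-n posterior selection matches a full-sort oracle", {
  set.seed(21)
  P <- matrix(stats::rnorm(1500, sd = 10), ncol = 3)
  m <- trimesh(P, cbind(1:500, c(2:500, 1), c(3:500, 1, 2)), clean = FALSE)
  cen <- c(0, 5, 0)  # everything with y < 5 is a candidate
  got <- pll_attachment(m, cen, 20L)
  cand <- which(P[, 2] < 5)
  d <- sqrt(rowSums(sweep(P[cand, ], 2, cen)^2))
  want <- cand[order(d, cand)][1:20]
  expect_identical(got, want)
  expect_identical(pll_attachment(m, cen, 1L), want[1])
  all_cand <- suppressWarnings(pll_attachment(m, cen, length(cand) + 50L))
  expect_setequal(all_cand, cand)
})

test_that("ligamentum flavum midpoints are symmetric exact midpoints", {
  expect_equal(lf_midpoints(c(0, 0, 0), c(0, 0, 10)), c(0, 0, 5))
  a <- c(1, -2, 3)
  b <- c(-4, 5, 0.5)
  expect_equal(lf_midpoints(a, b), lf_midpoints(b, a))
  expect_error(lf_midpoints(a, a), "coincident")
})

test_that("the default ligament table carries the published parameters", {
  tb <- default_ligament_table()
  expect_length(tb, 11L)
  expect_equal(unlist(tb$ALL_lower$coords[c("phi", "theta", "r")]),
               c(phi = 29.063, theta = -85, r = 18))
  expect_equal(unlist(tb$SSL_ISL$coords[c("phi", "theta", "r")]),
               c(phi = 25, theta = 90.7, r = -30))
  expect_equal(unlist(tb$CL_upper_right$coords[c("phi", "theta", "r")]),
               c(phi = -4, theta = 140, r = -27))
  plane_specs <- Filter(function(s) s$mode == "plane", tb)
  expect_length(plane_specs, 9L)
  expect_true(all(vapply(tb, `[[`, 0L, "n_springs") == 10L))
  expect_equal(tb$PLL$mode, "closest_n")
  expect_equal(tb$LF$mode, "midpoint")
})

test_that("a motion segment yields 8 ligament instances of 10 springs each", {
  p <- spine_params(seed = 1, mesh_subdiv = 3)
  v1 <- make_vertebra(p, 1)
  v2 <- make_vertebra(p, 2)
  sg <- segment_ligaments(v1, v2, parts = c("L1_cortical", "L2_cortical"))
  expect_length(sg, 8L)
  expect_true(all(vapply(sg, function(s) nrow(s$endpoints), 0L) == 10L))
  expect_true(all(vapply(sg, function(s) all(s$endpoints$rest_length > 0), TRUE)))
  # every endpoint is an existing mesh vertex
  for (s in sg) {
    expect_true(all(s$endpoints$node_upper <= nrow(v1$vertices)))
    expect_true(all(s$endpoints$node_lower <= nrow(v2$vertices)))
  }
})

test_that("attachment selection commutes with translations", {
  v <- make_vertebra(spine_params(seed = 14, mesh_subdiv = 3), 2)
  cen <- centroid(v)
  coord <- spherical_coordinate(35, 30, -1)
  a <- attachment_region(v, cen, coord)
  vt <- translate_mesh(v, c(7, -3, 12))
  b <- attachment_region(vt, centroid(vt), coord)
  expect_identical(a, b)
})
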