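# endplate extraction on an axis-aligned ellipsoid body and on synthetic
# vertebrae; the radial-shrink steps are checked against exact order-statistic
# arithmetic

ellipsoid_body <- function(a = 20, b = 15, c = 15, subdiv = 4L) {
  s <- icosphere(subdiv)
  s$vertices <- s$vertices %*% diag(c(a, b, c))
  s
}

test_that("the light direction is the least-variance axis, sign-fixed to +z", {
  slab <- ellipsoid_body(20, 15, 5)
  expect_equal(abs(light_direction(slab)[3]), 1, tolerance = 1e-6)
  expect_gt(light_direction(slab)[3], 0)
  # equivariance under a moderate rotation
  th <- 30 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  Ls <- light_direction(rotate_mesh(slab, R))
  expect_lt(max(abs(Ls - R %*% light_direction(slab))), 1e-6)
  # isotropic cloud: deterministic tie-break toward the z-aligned eigenvector
  iso <- icosphere(3, 10)
  L1 <- light_direction(iso)
  L2 <- light_direction(iso)
  expect_identical(L1, L2)
  expect_gt(abs(L1[3]), 1 / sqrt(3) - 1e-6)
})

test_that("radial shrink steps match exact order-statistic arithmetic", {
  # 10 points at planar radii exactly 1..10 mm about their own centroid:
  # eight fixed directions plus two solved so the radius-weighted directions
  # cancel and the centroid is the origin
  r <- 1:10
  ang8 <- c(0, pi / 2, pi, 3 * pi / 2, pi / 4, 5 * pi / 4, 3 * pi / 4, 7 * pi / 4)
  S <- colSums(r[1:8] * cbind(cos(ang8), sin(ang8)))
  # solve 9 u9 + 10 u10 = -S with unit u9, u10 (triangle construction)
  d <- sqrt(sum(S^2))
  phi <- atan2(-S[2], -S[1])
  cosg <- (d^2 + 81 - 100) / (2 * d * 9)
  g <- acos(pmin(1, pmax(-1, cosg)))
  u9 <- c(cos(phi + g), sin(phi + g))
  u10 <- (-S - 9 * u9) / 10
  P <- rbind(r[1:8] * cbind(cos(ang8), sin(ang8)), 9 * u9, 10 * u10)
  P3 <- cbind(P, 0)
  expect_lt(max(abs(colMeans(P3))), 1e-9)
  rr <- sqrt(rowSums(P^2))
  expect_equal(sort(rr), as.numeric(1:10), tolerance = 1e-9)
  L <- c(0, 0, 1)
  keep70 <- radial_keep_percentile(P3, L, 70)
  expect_identical(which(keep70), which(rr <= 7.3 + 1e-9))
  expect_equal(sum(keep70), 7L)
  keep55 <- radial_keep_fraction(P3, L, 0.55)
  expect_identical(which(keep55), which(rr <= 5.5 + 1e-9))
  expect_equal(sum(keep55), 5L)
})

test_that("upper endplate extraction lands on the top pole of an ellipsoid body", {
  body <- ellipsoid_body(20, 15, 15)
  up <- extract_upper_endplate(body)
  expect_gt(length(up$vertex_indices), 10)
  expect_lt(sqrt(sum((up$centroid[1:2] - c(0, 0))^2)), 1)
  zs <- body$vertices[up$vertex_indices, 3]
  expect_true(all(zs > 0))  # top half only
  N <- face_normals(body)
  expect_true(all(N[up$face_indices, ] %*% up$light > 0))
})

test_that("the largest candidate cluster wins", {
  # two flat patches 10 mm apart at the same height, sizes ~80 and ~20
  mk_patch <- function(n_side, x0) {
    g <- expand.grid(x = seq_len(n_side), y = seq_len(n_side))
    cbind(g$x * 0.5 + x0, g$y * 0.5, 10)
  }
  P <- rbind(mk_patch(9, 0), mk_patch(4, 30))   # 81 + 16 points
  lab <- spineforge:::.cluster_at(P, 1.5)
  sizes <- tabulate(lab)
  expect_equal(sort(sizes, decreasing = TRUE), c(81L, 16L))
})

test_that("lower endplate extraction respects the plane offset and disjointness", {
  body <- ellipsoid_body(20, 15, 15)
  up <- extract_upper_endplate(body)
  lo <- extract_lower_endplate(body, up)
  expect_lt(sqrt(sum((lo$centroid[1:2] - c(0, 0))^2)), 1)
  expect_true(all(body$vertices[lo$vertex_indices, 3] < 0))
  expect_length(intersect(up$vertex_indices, lo$vertex_indices), 0L)
  N <- face_normals(body)
  expect_true(all(N[lo$face_indices, ] %*% lo$light < 0))
  # a short vertebra cannot host the 20 mm offset plane
  short <- ellipsoid_body(20, 15, 7)  # 14 mm tall
  ups <- extract_upper_endplate(short)
  expect_error(extract_lower_endplate(short, ups), "lower_offset")
})

test_that("shrinkage is monotone: tighter thresholds give subsets", {
  v <- make_vertebra(spine_params(seed = 12), 3)
  p70 <- extract_upper_endplate(v, endplate_params(upper_keep_percentile = 70))
  p50 <- extract_upper_endplate(v, endplate_params(upper_keep_percentile = 50))
  expect_true(all(p50$vertex_indices %in% p70$vertex_indices))
  up <- extract_upper_endplate(v)
  l55 <- extract_lower_endplate(v, up, endplate_params(lower_keep_fraction = 0.55))
  l40 <- extract_lower_endplate(v, up, endplate_params(lower_keep_fraction = 0.40))
  expect_true(all(l40$vertex_indices %in% l55$vertex_indices))
})

test_that("endplate extraction commutes with moderate rigid motions", {
  v <- make_vertebra(spine_params(seed = 8), 2)
  set.seed(19)
  R <- random_rotation(max_angle = 30 * pi / 180)
  tr <- c(4, -11, 6)
  ep <- extract_endplates(v)
  epR <- extract_endplates(translate_mesh(rotate_mesh(v, R), tr))
  expect_identical(ep$upper$vertex_indices, epR$upper$vertex_indices)
  expect_identical(ep$lower$vertex_indices, epR$lower$vertex_indices)
  moved <- sweep(v$vertices[ep$upper$vertex_indices, , drop = FALSE] %*% t(R),
                 2, tr, "+")
  got <- translate_mesh(rotate_mesh(v, R), tr)$vertices[epR$upper$vertex_indices, ]
  expect_lt(max(abs(moved - got)), 1e-6)
})
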