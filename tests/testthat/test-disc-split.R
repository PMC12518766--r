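test_that("PCA frame has the documented normalization, ordering and signs", {
  # plane-confined points: zero variance along z
  set.seed(3)
  P <- cbind(stats::rnorm(200, sd = 3), stats::rnorm(200, sd = 2), 0)
  fr <- pca_frame(P)
  expect_equal(abs(fr$axes[3, 3]), 1, tolerance = 1e-10)
  expect_equal(fr$variances[3], 0, tolerance = 1e-10)
  # covariance uses 1/(n-1): check against cov()
  S <- stats::cov(P)
  expect_equal(sort(fr$variances, decreasing = TRUE),
               sort(eigen(S)$values, decreasing = TRUE), tolerance = 1e-10)
  # anisotropic cloud recovers the generation axes
  set.seed(4)
  Q <- cbind(stats::rnorm(1e4, sd = 3), stats::rnorm(1e4, sd = 2),
             stats::rnorm(1e4, sd = 0.5))
  fq <- pca_frame(Q)
  for (k in 1:3) {
    e <- c(0, 0, 0)
    e[k] <- 1
    expect_lt(acos(pmin(1, abs(sum(fq$axes[, k] * e)))) * 180 / pi, 3)
  }
  # two points: rank-1 frame along the segment
  f2 <- pca_frame(rbind(c(0, 0, 0), c(1, 1, 0)))
  expect_equal(f2$variances[2:3], c(0, 0), tolerance = 1e-12)
  expect_equal(abs(sum(f2$axes[, 1] * c(1, 1, 0) / sqrt(2))), 1, tolerance = 1e-10)
  # orthonormal right-handed triad
  A <- fq$axes
  expect_lt(max(abs(crossprod(A) - diag(3))), 1e-10)
  expect_gt(det(A), 0)
})

test_that("disc boundary curve matches analytic cross-sections and resampling", {
  p <- spine_params(seed = 9, noise_amplitude = 0)
  d <- make_disc(p, 1)
  fr <- pca_frame(d$vertices)
  cv <- disc_boundary_curve(d, fr, 64L)
  expect_equal(nrow(cv$points), 64L)
  # Ramanujan perimeter of the (18, 13) ellipse
  a <- 18; b <- 13
  h <- ((a - b) / (a + b))^2
  per_ell <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  per <- spineforge:::.curve_perimeter(cv$points)
  expect_lt(abs(per - per_ell) / per_ell, 0.02)
  # equal arc steps
  P <- cv$points
  seg <- sqrt(rowSums((P[c(2:64, 1), ] - P)^2))
  expect_lt(diff(range(seg)) / mean(seg), 0.01)
  expect_error(disc_boundary_curve(d, fr, 4L), "n_samples")
})

test_that("boundary points of a circular disc sit at the analytic radius", {
  # circular cylinder: equal transverse semi-axes
  p <- spine_params(seed = 2, disc_radii = c(12, 12), noise_amplitude = 0)
  d <- make_disc(p, 1)
  fr <- pca_frame(d$vertices)
  cv <- disc_boundary_curve(d, fr, 64L)
  cen <- colMeans(cv$points)
  r <- sqrt(rowSums(sweep(cv$points, 2, cen)^2))
  expect_true(all(abs(r - 12) / 12 < 0.02))
})

test_that("curve scaling is an exact similarity about the centroid", {
  th <- 2 * pi * (0:31) / 32
  circ <- boundary_curve(cbind(cos(th), sin(th), 0),
                         pca_frame(cbind(cos(th), sin(th), 0)))
  expect_equal(scale_curve(circ, 1)$points, circ$points)
  half <- scale_curve(circ, 0.5)
  expect_true(all(abs(sqrt(rowSums(half$points[, 1:2]^2)) - 0.5) < 1e-12))
  s6 <- scale_curve(circ, 0.6)
  expect_equal(spineforge:::.curve_perimeter(s6$points),
               0.6 * spineforge:::.curve_perimeter(circ$points),
               tolerance = 1e-9)
  expect_error(scale_curve(circ, 0), "scale")
  expect_error(scale_curve(circ, 1.2), "scale")
})

test_that("the swept nucleus solid matches the analytic clipped cylinder", {
  # circular-cylinder disc (radius 12, height 10)
  p <- spine_params(seed = 2, disc_radii = c(12, 12), noise_amplitude = 0)
  d <- make_disc(p, 1)
  fr <- pca_frame(d$vertices)
  cv <- disc_boundary_curve(d, fr, 64L)
  half <- scale_curve(cv, 0.5)
  nuc <- build_nucleus_solid(half, d, point_spacing = 1)
  expect_true(is_closed(nuc))
  expect_lt(abs(enclosed_volume(nuc) - pi * 6^2 * 10) / (pi * 6^2 * 10), 0.05)
  # s = 1: nucleus fills nearly the whole disc
  full <- build_nucleus_solid(scale_curve(cv, 1), d, point_spacing = 1)
  expect_lt(abs(enclosed_volume(full) - enclosed_volume(d)) /
              enclosed_volume(d), 0.08)
  # clipping contract: every nucleus vertex inside or on the disc
  d_out <- spineforge:::cpp_dist_to_mesh(d$vertices, d$faces, nuc$vertices)
  inside <- point_in_mesh(d, nuc$vertices)
  expect_true(all(inside | d_out < 1e-6))
})

test_that("centroid alignment is an exact rigid translation", {
  s <- icosphere(2, 4)
  ref <- translate_mesh(icosphere(3, 6), c(5, -2, 8))
  moved <- align_centroids(translate_mesh(s, c(1, 2, 3)), ref)
  expect_equal(centroid(moved), centroid(ref), tolerance = 1e-12)
  d0 <- as.matrix(dist(s$vertices[1:50, ]))
  d1 <- as.matrix(dist(moved$vertices[1:50, ]))
  expect_lt(max(abs(d0 - d1)), 1e-12)
  expect_equal(align_centroids(ref, ref)$vertices, ref$vertices)
})

test_that("face partition follows the any-vertex-inside rule exactly", {
  d <- icosphere(2, 1)
  big <- icosphere(3, 10)
  part <- partition_disc_faces(d, big)
  expect_length(part$nucleus_faces, nrow(d$faces))
  far <- translate_mesh(icosphere(3, 1), c(50, 0, 0))
  part2 <- partition_disc_faces(d, far)
  expect_length(part2$annulus_faces, nrow(d$faces))
  # concentric half-radius sphere: all surface vertices outside it
  small <- icosphere(3, 0.5)
  part3 <- partition_disc_faces(d, small)
  expect_length(part3$nucleus_faces, 0L)
  # exhaustive + exclusive
  expect_equal(sort(c(part$nucleus_faces, part$annulus_faces)),
               seq_len(nrow(d$faces)))
})

test_that("top/bottom split thresholds at the centroid z midrange", {
  # cylinder-like fixture with caps at z = 0 and z = 10
  th <- 2 * pi * (0:15) / 16
  ring0 <- cbind(cos(th), sin(th), 0)
  ring1 <- cbind(cos(th), sin(th), 10)
  V <- rbind(ring0, ring1, c(0, 0, 0), c(0, 0, 10))
  n <- 16L
  nx <- c(2:n, 1L)
  F <- rbind(cbind(seq_len(n), nx, n + nx), cbind(seq_len(n), n + nx, n + seq_len(n)),
             cbind(2L * n + 1L, nx, seq_len(n)),
             cbind(2L * n + 2L, n + seq_len(n), n + nx))
  cyl <- trimesh(V, F)
  sp <- split_top_bottom(cyl, seq_len(nrow(F)))
  expect_equal(sp$z_threshold, 5)
  cen_z <- (V[F[, 1], 3] + V[F[, 2], 3] + V[F[, 3], 3]) / 3
  expect_true(all(cen_z[match(sp$top, seq_len(nrow(F)))] > 5))
  expect_true(all(cen_z[match(sp$bottom, seq_len(nrow(F)))] <= 5))
})

test_that("lofting corresponds cyclically and rejects degenerate strips", {
  th <- 2 * pi * (0:31) / 32
  fr <- pca_frame(cbind(cos(th), sin(th), 0))
  top <- boundary_curve(cbind(cos(th), sin(th), 1), fr)
  bot <- boundary_curve(cbind(cos(th), sin(th), 0), fr)
  w <- loft_walls(top, bot)
  expect_equal(nrow(w$faces), 64L)
  expect_equal(nrow(boundary_edges(w)), 64L)  # two open rims of 32 edges
  # rotated bottom curve: same surface after cyclic alignment
  shift <- c(9:32, 1:8)
  w2 <- loft_walls(top, boundary_curve(bot$points[shift, ], fr))
  a1 <- sum(spineforge:::.face_area(w$vertices, w$faces))
  a2 <- sum(spineforge:::.face_area(w2$vertices, w2$faces))
  expect_lt(abs(a1 - a2), 1e-9)
  expect_error(loft_walls(top, top), "degenerate")
  bad <- boundary_curve(bot$points[1:16, ], fr)
  expect_error(loft_walls(top, bad), "counts differ")
})

test_that("disc separation is watertight, conservative and shares wall nodes", {
  p <- spine_params(seed = 42)
  d <- make_disc(p, 1)
  dp <- split_disc(d)
  expect_s3_class(dp, "disc_partition")
  # exact partition
  expect_equal(sort(c(dp$nucleus_faces, dp$annulus_faces)), seq_len(nrow(d$faces)))
  expect_length(intersect(dp$nucleus_faces, dp$annulus_faces), 0L)
  # watertight outputs
  expect_true(is_closed(dp$nucleus_mesh))
  expect_true(is_closed(dp$annulus_mesh))
  # volume conservation of the solids
  vd <- enclosed_volume(d)
  closure <- (tet_volume(dp$nucleus_solid) + tet_volume(dp$annulus_solid)) / vd
  expect_lt(abs(closure - 1), 0.03)
  # interface nodes present in both solids with identical coordinates
  key <- function(M) sprintf("%.10f %.10f %.10f", M[, 1], M[, 2], M[, 3])
  expect_true(all(key(dp$wall$vertices) %in% key(dp$nucleus_solid$vertices)))
  expect_true(all(key(dp$wall$vertices) %in% key(dp$annulus_solid$vertices)))
})

test_that("nucleus volume grows with the scale factor", {
  p <- spine_params(seed = 7)
  d <- make_disc(p, 2)
  v5 <- tet_volume(split_disc(d, scale = 0.5)$nucleus_solid)
  v7 <- tet_volume(split_disc(d, scale = 0.7)$nucleus_solid)
  expect_lt(v5, v7)
})
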