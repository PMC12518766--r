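# parallel-patch fixture: two congruent circular disc patches a fixed gap
# apart, the analytic slab volume as oracle
circle_patch <- function(radius = 10, z = 0, n_ring = 6L, n_th = 24L) {
  pts <- c(0, 0, z)
  for (j in seq_len(n_ring)) {
    th <- 2 * pi * (0:(n_th - 1)) / n_th
    pts <- rbind(pts, cbind(radius * j / n_ring * cos(th),
                            radius * j / n_ring * sin(th), z))
  }
  V <- matrix(pts, ncol = 3)
  F <- NULL
  ring <- function(j) 1L + (j - 1L) * n_th + seq_len(n_th)
  nx <- c(2:n_th, 1L)
  F <- rbind(F, cbind(1L, ring(1L), ring(1L)[nx]))
  for (j in seq_len(n_ring - 1L)) {
    a <- ring(j)
    b <- ring(j + 1L)
    F <- rbind(F, cbind(a, b, b[nx]), cbind(a, b[nx], a[nx]))
  }
  trimesh(V, F)
}

fake_patch <- function(mesh, normal_sign = -1) {
  # wrap a free-standing mesh as an endplate patch facing `normal_sign * z`
  structure(list(vertex_indices = seq_len(nrow(mesh$vertices)),
                 faces = mesh$faces,
                 face_indices = seq_len(nrow(mesh$faces)),
                 plane = list(point = centroid(mesh),
                              normal = c(0, 0, normal_sign)),
                 centroid = centroid(mesh), light = c(0, 0, 1),
                 side = if (normal_sign > 0) "upper" else "lower",
                 mesh = mesh),
            class = "endplate_patch")
}

test_that("contact faces select the facing cap within the gap threshold", {
  upper <- circle_patch(10, z = 0.5)       # endplate 0.5 mm above the disc cap
  disc_cap <- circle_patch(10, z = 0)
  patch <- fake_patch(upper, normal_sign = -1)
  sel <- contact_faces(disc_cap, patch, max_gap = 1)
  expect_setequal(sel, seq_len(nrow(disc_cap$faces)))
  expect_warning(none <- contact_faces(disc_cap, patch, max_gap = 0.1),
                 "no contact faces")
  expect_length(none, 0L)
  # subset contract
  expect_true(all(sel <= nrow(disc_cap$faces)))
  expect_error(contact_faces(disc_cap, patch, max_gap = -1), "max_gap")
})

test_that("cartilage between parallel circular patches matches the slab volume", {
  upper <- circle_patch(10, z = 1)
  lower <- circle_patch(10, z = 0)
  patch <- fake_patch(upper, normal_sign = -1)
  nc <- contact_faces(lower, patch, max_gap = 2)
  seg <- build_cartilage(patch, lower, nc, lower, integer(0), label = "T1",
                         max_gap = 2)
  expect_true(is_closed(seg$surface))
  vol <- tet_volume(seg$solid)
  expect_lt(abs(vol - pi * 100) / (pi * 100), 0.10)
  expect_error(build_cartilage(patch, lower, integer(0), lower, integer(0),
                               label = "T1"), "empty")
})

test_that("the synthetic stack yields exactly the eight labeled segments", {
  pl <- full_pipeline()
  expect_setequal(names(pl$cartilage),
                  c("L1D1", "L2D1", "L2D2", "L3D2", "L3D3", "L4D3", "L4D4", "L5D4"))
  expect_length(pl$cartilage, 2L * length(pl$discs))
  for (seg in pl$cartilage) {
    expect_true(is_closed(seg$surface))
    expect_gt(tet_volume(seg$solid), 0)
  }
})

test_that("cartilage stays between the endplate and the disc", {
  pl <- full_pipeline()
  seg <- pl$cartilage$L1D1
  # no interpenetration beyond the node tolerance: cartilage vertices are
  # never strictly inside the disc parts by more than 0.01 mm
  d1 <- pl$discs$D1
  inside <- point_in_mesh(d1$nucleus_mesh, seg$solid$vertices) |
    point_in_mesh(d1$annulus_mesh, seg$solid$vertices)
  if (any(inside)) {
    pts <- seg$solid$vertices[inside, , drop = FALSE]
    depth <- pmin(
      spineforge:::cpp_dist_to_mesh(d1$annulus_mesh$vertices,
                                    d1$annulus_mesh$faces, pts),
      spineforge:::cpp_dist_to_mesh(d1$nucleus_mesh$vertices,
                                    d1$nucleus_mesh$faces, pts))
    expect_lt(max(depth), 0.01 + 1e-9)
  } else succeed()
})
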