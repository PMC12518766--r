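test_that("face normals follow the right-hand rule and reject degenerate faces", {
  m <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  expect_equal(drop(face_normals(m)), c(0, 0, 1), tolerance = 1e-12)
  m2 <- trimesh(rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0)), rbind(c(1, 2, 3)))
  expect_equal(drop(face_normals(m2)), c(0, 0, -1), tolerance = 1e-12)
  m3 <- trimesh(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), rbind(c(1, 2, 3)),
                clean = FALSE)
  expect_error(face_normals(m3), "degenerate")
  # unit length on a generated fixture
  s <- icosphere(3, 7)
  expect_true(all(abs(sqrt(rowSums(face_normals(s)^2)) - 1) < 1e-12))
})

test_that("vertex normals are area-weighted and radial on a sphere", {
  s <- icosphere(3)
  vn <- vertex_normals(s)
  rad <- s$vertices / sqrt(rowSums(s$vertices^2))
  # exactly radial at the 12 fully symmetric base vertices; within the
  # discretization error (O(edge^2)) elsewhere
  expect_lt(max(abs(vn[1:12, ] - rad[1:12, ])), 1e-6)
  expect_lt(max(abs(vn - rad)), 0.02)
  # flat grid interior vertex: all incident normals identical
  g <- expand.grid(x = 0:3, y = 0:3)
  gv <- cbind(as.matrix(g), 0)
  gid <- function(i, j) i + 1L + j * 4L
  gf <- NULL
  for (j in 0:2) for (i in 0:2)
    gf <- rbind(gf, c(gid(i, j), gid(i + 1, j), gid(i + 1, j + 1)),
                c(gid(i, j), gid(i + 1, j + 1), gid(i, j + 1)))
  expect_equal(vertex_normals(trimesh(gv, gf))[gid(1, 1), ], c(0, 0, 1),
               tolerance = 1e-12)
  # apex of a symmetric square pyramid: average of slant normals is vertical
  V <- rbind(c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0), c(1, -1, 0), c(0, 0, 1))
  F <- rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5))
  vn <- vertex_normals(trimesh(V, F))
  expect_equal(vn[5, ], c(0, 0, 1), tolerance = 1e-12)
  # isolated vertex errors
  expect_error(vertex_normals(trimesh(rbind(V, c(9, 9, 9)), F, clean = FALSE)),
               "isolated")
})

test_that("Laplacian smoothing is synchronous, contractive and subset-aware", {
  # vertex above a symmetric hexagonal ring moves to the ring centroid
  th <- 2 * pi * (0:5) / 6
  V <- rbind(cbind(cos(th), sin(th), 0), c(0, 0, 1))
  F <- cbind(1:6, c(2:6, 1), 7)
  m <- trimesh(V, F)
  s1 <- laplacian_smooth(m, smoothing_params(1, 1), subset = 7L)
  expect_equal(s1$vertices[7, ], c(0, 0, 0), tolerance = 1e-12)
  s2 <- laplacian_smooth(m, smoothing_params(0.5, 1), subset = 7L)
  expect_equal(s2$vertices[7, ], c(0, 0, 0.5), tolerance = 1e-12)
  expect_equal(s2$faces, m$faces)
  # contraction bound: step <= lam * distance to 1-ring centroid
  s <- icosphere(2, 5)
  sm <- laplacian_smooth(s, smoothing_params(0.7, 1))
  step <- sqrt(rowSums((sm$vertices - s$vertices)^2))
  # centroid distance recovered from the lam=1 update
  full <- laplacian_smooth(s, smoothing_params(1, 1))
  dcen <- sqrt(rowSums((full$vertices - s$vertices)^2))
  expect_true(all(step <= 0.7 * dcen + 1e-12))
})

test_that("centroid handles the documented cases", {
  expect_equal(centroid(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))),
               c(1 / 3, 1 / 3, 0))
  expect_equal(centroid(matrix(c(2, 3, 4), 1)), c(2, 3, 4))
  expect_equal(centroid(as.matrix(expand.grid(0:1, 0:1, 0:1))),
               c(0.5, 0.5, 0.5), ignore_attr = TRUE)
  expect_error(centroid(matrix(0, 0, 3)), "empty")
})

test_that("enclosed volume is exact on the cube, near-analytic on the sphere,
           sign-flips with orientation, and rejects open meshes", {
  cb <- cube_mesh()
  expect_equal(enclosed_volume(cb), 1, tolerance = 1e-12)
  s <- icosphere(4, 10)
  expect_lt(abs(enclosed_volume(s) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.01)
  flipped <- cb
  flipped$faces <- flipped$faces[, c(1, 3, 2)]
  expect_equal(enclosed_volume(flipped), -1, tolerance = 1e-12)
  open <- trimesh(cb$vertices, cb$faces[-1, ], clean = FALSE)
  expect_error(enclosed_volume(open), "boundary edges")
  # rigid-motion invariance
  set.seed(7)
  for (i in 1:5) {
    R <- random_rotation()
    mr <- translate_mesh(rotate_mesh(s, R), stats::rnorm(3, sd = 40))
    expect_lt(abs(enclosed_volume(mr) - enclosed_volume(s)) /
                enclosed_volume(s), 1e-9)
  }
})

test_that("largest_component keeps the biggest patch with documented tie-breaks", {
  s <- icosphere(2, 5)                      # 320 faces
  blob <- translate_mesh(icosphere(0, 1), c(30, 0, 0))  # 20 faces
  V <- rbind(s$vertices, blob$vertices)
  F <- rbind(s$faces, blob$faces + nrow(s$vertices))
  lc <- largest_component(trimesh(V, F))
  expect_equal(nrow(lc$faces), nrow(s$faces))
  # single component: identity up to re-indexing
  lc2 <- largest_component(s)
  expect_equal(nrow(lc2$faces), nrow(s$faces))
  expect_equal(sort(apply(lc2$vertices, 1, paste, collapse = ",")),
               sort(apply(s$vertices, 1, paste, collapse = ",")))
  # two identical blobs: the one containing global vertex index 1 wins
  b2 <- translate_mesh(icosphere(0, 1), c(10, 0, 0))
  VV <- rbind(icosphere(0, 1)$vertices, b2$vertices)
  FF <- rbind(icosphere(0, 1)$faces, b2$faces + 12L)
  lc3 <- largest_component(trimesh(VV, FF))
  expect_lt(max(abs(lc3$vertices - icosphere(0, 1)$vertices)), 1e-12)
})

test_that("fill_holes triangulates small loops and reports skipped ones", {
  cb <- cube_mesh()
  open <- trimesh(cb$vertices, cb$faces[-c(1, 2), ], clean = FALSE)  # one quad gone
  filled <- fill_holes(open, max_perimeter = 10)
  expect_true(is_closed(filled))
  nv <- nrow(filled$vertices)
  ne <- length(edge_lengths(filled))
  nf <- nrow(filled$faces)
  expect_equal(nv - ne + nf, 2)  # Euler characteristic of a sphere
  expect_equal(attr(filled, "filled_loops"), 1L)
  # orientation stays consistent outward
  expect_equal(enclosed_volume(filled), 1, tolerance = 1e-12)
  # closed input untouched
  same <- fill_holes(cb, 10)
  expect_equal(same$faces, cb$faces)
  # threshold excludes the hole
  skipped <- fill_holes(open, max_perimeter = 0.1)
  expect_false(is_closed(skipped))
  expect_equal(attr(skipped, "skipped_loops"), 1L)
})

test_that("point_in_mesh matches analytic membership and brute-force parity", {
  s <- icosphere(3, 1)
  expect_true(point_in_mesh(s, matrix(0, 1, 3)))
  expect_false(point_in_mesh(s, matrix(c(2, 0, 0), 1)))
  set.seed(11)
  pts <- matrix(stats::runif(3000, -2, 2), ncol = 3)
  got <- point_in_mesh(s, pts)
  r <- sqrt(rowSums(pts^2))
  # facet sag of the subdivided sphere: only clear-side points are judged
  sag <- 1 - sqrt(1 - (0.135 / 2)^2)
  clear <- abs(r - 1) > 2 * sag
  expect_equal(got[clear], (r < 1)[clear])
  expect_error(point_in_mesh(trimesh(s$vertices, s$faces[-1, ], clean = FALSE),
                             pts), "open")
})

test_that("point_in_mesh agrees with an independent parity oracle on small meshes", {
  set.seed(23)
  blob <- icosphere(2, 3)  # 320 faces <= 500
  blob$vertices <- blob$vertices * (1 + 0.1 * sin(3 * blob$vertices[, 1]))
  pts <- matrix(stats::runif(900, -4, 4), ncol = 3)
  expect_equal(point_in_mesh(blob, pts), brute_inside(blob, pts))
})

test_that("isotropic remeshing hits the target edge and conserves volume", {
  s <- icosphere(4, 10)
  r1 <- remesh_isotropic(s, 1.0)
  expect_true(is_closed(r1))
  med <- stats::median(edge_lengths(r1))
  expect_gt(med, 0.75)
  expect_lt(med, 1.25)
  expect_lt(abs(enclosed_volume(r1) - enclosed_volume(s)) / enclosed_volume(s),
            0.01)
  # stability: remeshing at the current median keeps the face count comparable
  cur <- stats::median(edge_lengths(s))
  r2 <- remesh_isotropic(s, cur)
  expect_lt(nrow(r2$faces), 2 * nrow(s$faces))
  expect_gt(nrow(r2$faces), nrow(s$faces) / 2)
  expect_error(remesh_isotropic(s, -1), "positive")
})

test_that("tetrahedralization is boundary-exact and volume-consistent", {
  cb <- cube_mesh()
  tm <- tetrahedralize(cb)
  expect_equal(tet_volume(tm), 1, tolerance = 1e-6)
  expect_true(all(tet_volume(tm, per_cell = TRUE) > 0))
  s <- icosphere(3, 10)
  ts <- tetrahedralize(s)
  expect_lt(abs(tet_volume(ts) - enclosed_volume(s)) / enclosed_volume(s), 1e-3)
  # refinement respects the volume cap and total volume
  tr <- tetrahedralize(cb, max_cell_volume = 0.05)
  expect_true(all(tet_volume(tr, per_cell = TRUE) <= 0.05 + 1e-12))
  expect_equal(tet_volume(tr), 1, tolerance = 1e-9)
  # open surface rejected
  expect_error(tetrahedralize(trimesh(s$vertices, s$faces[-1, ], clean = FALSE)),
               "open")
})

test_that("mesh I/O round-trips through STL, VTK PolyData and OBJ", {
  s <- icosphere(2, 7.5)
  stl <- file.path(tempdir(), "io_test.stl")
  write_stl(s, stl)
  back <- read_stl(stl)
  expect_equal(nrow(back$faces), nrow(s$faces))
  expect_equal(enclosed_volume(back), enclosed_volume(s), tolerance = 1e-5)
  vtk <- file.path(tempdir(), "io_test.vtk")
  write_vtk_polydata(s, vtk)
  bv <- read_vtk_polydata(vtk)
  expect_equal(bv$faces, s$faces)
  expect_lt(max(abs(bv$vertices - s$vertices)), 1e-9)
  obj <- file.path(tempdir(), "io_test.obj")
  writeLines(c(sprintf("v %.9f %.9f %.9f", s$vertices[, 1], s$vertices[, 2],
                       s$vertices[, 3]),
               sprintf("f %d %d %d", s$faces[, 1], s$faces[, 2], s$faces[, 3])),
             obj)
  bo <- read_obj(obj)
  expect_equal(bo$faces, s$faces)
})
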