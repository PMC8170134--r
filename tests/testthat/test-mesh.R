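# Two-layer hexahedral meshing, fibers, region labels, VTK export.

test_that("annulus mesh reproduces the wall volume closed form", {
  st <- make_cylinder_stack(n_s = 5, n_t = 48, ri = 20, ro = 30, h = 60)
  m <- build_mesh(st, n_theta_mesh = 48)
  vol <- sum(element_volumes(m))
  expect_equal(vol / 1000, pi * (900 - 400) * 60 / 1000,
               tolerance = 0.02 * pi * 500 * 60 / 1000)
  expect_setequal(unique(m$layer), c("inner", "outer"))
  expect_gt(min(mesh_quality(m)), 0)
})

test_that("bi-ventricular mesh has exactly two layers and labeled regions", {
  m <- small_biventricle()
  expect_setequal(unique(m$layer), c("inner", "outer"))
  expect_true(all(m$region %in% c("LV", "RV", "septum")))
  # labels partition the element set
  expect_length(m$region, nrow(m$elems))
  expect_false(anyNA(m$region))
  expect_gt(min(mesh_quality(m)), 0)
})

test_that("crossed contours are rejected at meshing", {
  st <- make_cylinder_stack(n_s = 4, n_t = 24, ri = 28, ro = 30)
  st$slices[[2]]$lv_inner <- st$slices[[2]]$lv_inner * 1.2  # inner outside outer
  expect_error(build_mesh(st, n_theta_mesh = 24), "inner contour outside")
})

test_that("fiber field is unit-norm, tangent, and at the prescribed angles", {
  m <- small_biventricle()
  expect_true(all(abs(sqrt(rowSums(m$fiber^2)) - 1) < 1e-9))
  # LV outer element near the equator: fiber at -60 deg from circumferential
  cen <- t(vapply(seq_len(nrow(m$elems)), function(e)
    colMeans(m$nodes[m$elems[e, ], ]), numeric(3)))
  cand <- which(m$body == "LV" & m$layer == "outer" & abs(cen[, 3]) < 6)
  e <- cand[which.max(cen[cand, 1])]
  phi <- atan2(cen[e, 2], cen[e, 1])
  e_c <- c(-sin(phi), cos(phi), 0)
  e_l <- c(0, 0, 1)
  expected <- cos(-60 * pi / 180) * e_c + sin(-60 * pi / 180) * e_l
  ang <- acos(min(1, abs(sum(m$fiber[e, ] * expected))))
  expect_lt(ang, 0.05)   # coarse mesh: small discretization tilt
  # Rodrigues-rotation oracle on sampled RV inner elements (+40 deg)
  rv_in <- which(m$body == "RV" & m$layer == "inner" & m$region == "RV")
  set.seed(5)
  for (e in sample(rv_in, 10)) {
    nd <- m$elems[e, ]
    lo <- colMeans(m$nodes[nd[c(1, 4, 5, 8)], ])
    hi <- colMeans(m$nodes[nd[c(2, 3, 6, 7)], ])
    nrm <- (hi - lo) / sqrt(sum((hi - lo)^2))
    zv <- c(0, 0, 1)
    ec <- pracma_cross(zv, nrm); ec <- ec / sqrt(sum(ec^2))
    expected <- rodrigues(ec, nrm, 40 * pi / 180)
    expect_equal(abs(sum(m$fiber[e, ] * expected)), 1, tolerance = 1e-6)
  }
  # zero angles give pure circumferential fibers
  m0 <- assign_fibers(small_biventricle(), lv_angles = c(0, 0),
                      rv_angles = c(0, 0))
  lv_e <- which(m0$body == "LV")[1:20]
  for (e in lv_e) expect_lt(abs(m0$fiber[e, 3]), 1e-9)
})

test_that("scar and patch labeling respects the free wall and extents", {
  m <- small_biventricle()
  m2 <- label_regions(m,
                      scar_spec = list(center_deg = -25, half_width_deg = 15,
                                       slices = 2:3),
                      patch_spec = list(center_deg = 25, half_width_deg = 15,
                                        slices = 2:3))
  expect_gt(sum(m2$region == "scar"), 0)
  expect_gt(sum(m2$region == "patch"), 0)
  # contiguity: patch elements are adjacent in (k, slice) index space
  pk <- m2$elem_tab[m2$region == "patch", "k"]
  expect_lte(diff(range(pk)), length(unique(pk)))
  # zero extent labels nothing
  m3 <- label_regions(m, scar_spec = list(center_deg = 0, half_width_deg = 0,
                                          slices = 2))
  expect_equal(sum(m3$region == "scar"), 0)
  # overlapping specs rejected
  expect_error(label_regions(m,
    scar_spec = list(center_deg = 0, half_width_deg = 20, slices = 2:3),
    patch_spec = list(center_deg = 10, half_width_deg = 20, slices = 2:3)),
    "overlap")
  # spec outside the RV free wall rejected
  expect_error(label_regions(m,
    patch_spec = list(center_deg = 180, half_width_deg = 10, slices = 2)),
    "outside the RV free wall")
})

test_that("VTK export writes a well-formed legacy unstructured grid", {
  m <- small_biventricle()
  f <- tempfile(fileext = ".vtk")
  write_vtk_mesh(m, f, disp = 0 * m$nodes)
  lines <- readLines(f)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^DATASET UNSTRUCTURED_GRID", lines)))
  expect_true(any(grepl(sprintf("^POINTS %d double", nrow(m$nodes)), lines)))
  expect_true(any(grepl(sprintf("^CELLS %d", nrow(m$elems)), lines)))
  expect_true(any(grepl("^SCALARS region int", lines)))
  expect_true(any(grepl("^VECTORS fiber double", lines)))
  expect_true(any(grepl("^VECTORS displacement double", lines)))
  # all cells are hexahedra (VTK type 12)
  ct <- which(grepl("^CELL_TYPES", lines))
  expect_true(all(lines[(ct + 1):(ct + nrow(m$elems))] == "12"))
})
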