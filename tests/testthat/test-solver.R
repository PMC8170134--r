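# Quasi-static equilibrium solver, cavity volumes, cycle machinery.

test_that("zero pressure with a slack band gives zero displacement", {
  pm <- small_patient()
  sys <- fe_system(pm$mesh)
  mp <- material_matrix(pm$mesh, pm$materials, 0, pm$scales)
  sol <- solve_equilibrium(sys, mp, 0, 0)
  expect_lt(max(abs(sol$u)), 1e-8)
})

test_that("pressurized thick-walled shell matches the incompressible closed form", {
  st <- make_cylinder_stack(n_s = 5, n_t = 36, ri = 20, ro = 30, h = 40)
  m <- assign_fibers(build_mesh(st, n_theta_mesh = 32, n_layers = 4))
  sys <- fe_system(m, fix_all_z = TRUE)
  c1 <- 10
  M <- nrow(m$elems)
  mp <- matrix(rep(c(c1, 0, 0, 0, 0, 1, 200 * c1), each = M), M, 7)
  p <- 2.0
  sol <- solve_equilibrium(sys, mp, p_rv = 0, p_lv = p)
  inner <- unique(as.vector(m$grids$LV[, , 1]))
  x <- m$nodes + sol$u
  ri_fe <- mean(sqrt(x[inner, 1]^2 + x[inner, 2]^2))
  ri_or <- cylinder_oracle_ri(p, c1 = c1)
  expect_equal(ri_fe, ri_or, tolerance = 0.02 * ri_or)
  # near-incompressibility of the wall under the penalty
  fl <- ventriband:::fe_fields(m$nodes, m$elems, sol$u, mp, m$fiber)
  expect_true(all(abs(fl$J - 1) < 0.02))
})

test_that("RV volume increases monotonically with RV pressure", {
  pm <- small_patient()
  sys <- fe_system(pm$mesh)
  mp <- material_matrix(pm$mesh, pm$materials, 0, pm$scales)
  u0 <- NULL
  vols <- vapply(c(1, 2, 3, 4), function(p) {
    sol <- solve_equilibrium(sys, mp, p, 2 * p, u0 = u0)
    u0 <<- sol$u
    cavity_volume(pm$mesh, "RV", sol$u)
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("cavity volume: closed forms, translation invariance, refinement", {
  # cylinder pi r^2 h
  st <- make_cylinder_stack(n_s = 5, n_t = 48, ri = 20, ro = 30, h = 40)
  m <- build_mesh(st, n_theta_mesh = 48)
  expect_equal(cavity_volume(m, "LV"), pi * 400 * 40 / 1000,
               tolerance = 0.005 * pi * 400 * 40 / 1000)
  # translation leaves the volume unchanged
  shift <- matrix(rep(c(3, -2, 5), each = nrow(m$nodes)), ncol = 3)
  expect_equal(cavity_volume(m, "LV", shift), cavity_volume(m, "LV"),
               tolerance = 1e-10)
  # near-spherical cavity within 0.5% at fine resolution
  gp <- geom_params(lv_inner_radius = 25, lv_length = 25, lv_wall = 5,
                    include_rv = FALSE, apex_frac = 0.995, base_frac = 0.995)
  sph <- generate_contour_stack(gp, n_slices = 60, n_theta = 96)
  ms <- build_mesh(sph, n_theta_mesh = 96)
  expect_equal(cavity_volume(ms, "LV"), 4 / 3 * pi * 25^3 / 1000,
               tolerance = 0.005 * 4 / 3 * pi * 25^3 / 1000)
  # refinement sequence converges with shrinking error
  vs <- vapply(c(12, 24, 48), function(nt) {
    mm <- build_mesh(st, n_theta_mesh = nt)
    cavity_volume(mm, "LV")
  }, numeric(1))
  err <- abs(vs - pi * 400 * 40 / 1000)
  expect_true(all(diff(err) < 0))
  # order >= 2: quartering of the error when doubling resolution
  expect_lt(err[2] / err[1], 0.3)
  expect_error(cavity_volume(m, "RV"), "no RV")
})

test_that("cycle convergence metric: zero, scaling, quadrature oracle", {
  set.seed(9)
  a <- matrix(abs(rnorm(60)), 10, 6)
  w <- runif(10)
  expect_equal(cycle_convergence(list(stress_p1 = a, strain_p1 = a),
                                 list(stress_p1 = a, strain_p1 = a), w), 0)
  eps <- 1e-4
  m <- cycle_convergence(list(stress_p1 = a, strain_p1 = a),
                         list(stress_p1 = (1 + eps) * a,
                              strain_p1 = (1 + eps) * a), w)
  expect_equal(m, eps / (1 + eps), tolerance = 1e-12)
  # independent weighted-quadrature oracle
  b <- a + matrix(rnorm(60, 0, 0.05), 10, 6)
  m2 <- cycle_convergence(list(stress_p1 = a, strain_p1 = a),
                          list(stress_p1 = b, strain_p1 = b), w)
  oracle <- sqrt(sum(w * rowSums((a - b)^2))) / sqrt(sum(w * rowSums(b^2)))
  expect_equal(m2, oracle, tolerance = 1e-12)
  expect_error(cycle_convergence(list(stress_p1 = a, strain_p1 = a),
                                 list(stress_p1 = a[, 1:3],
                                      strain_p1 = a[, 1:3]), w),
               "mismatched")
})

test_that("band zero-stress schedule hits its anchors", {
  band <- list(ratio = 0.2, passive = FALSE)
  expect_equal(band_zero_stress_schedule(band, 0.4), 0.8)   # peak systole
  expect_equal(band_zero_stress_schedule(band, 0), 1)       # diastole anchor
  expect_equal(band_zero_stress_schedule(band, 0.2), 0.9)   # cosine midpoint
  passive <- list(ratio = 0, passive = TRUE)
  expect_true(all(band_zero_stress_schedule(passive, seq(0, 1, 0.1)) == 1))
  expect_error(band_zero_stress_schedule(list(ratio = 0.5), 0.2), "ratio")
})

test_that("baseline cycle reaches periodic convergence and the anchors", {
  pm <- small_patient()
  res <- simulate_cycle(vb_model(pm$mesh, pm$materials, pm$pressures,
                                 scales = pm$scales, u0 = pm$u_ed))
  expect_lt(min(res$convergence), 1e-3)
  expect_lte(res$cycles, 5)
  # cavity volumes at the anchors match the calibration targets
  expect_equal(res$edv, unname(pm$targets["edv"]),
               tolerance = 0.005 * pm$targets["edv"])
  expect_equal(res$esv, unname(pm$targets["esv"]),
               tolerance = 0.005 * pm$targets["esv"])
  expect_true(all(res$volumes$rv_volume_ml > 0))
  # total wall volume change over the cycle stays below 2%
  for (anc in names(res$anchors)) {
    fl <- res$anchors[[anc]]$fields
    v0 <- sum(fl$ref_volume)
    expect_lt(abs(sum(fl$J * fl$ref_volume) - v0) / v0, 0.02)
  }
  # determinism: rerun gives bit-identical EF
  res2 <- simulate_cycle(vb_model(pm$mesh, pm$materials, pm$pressures,
                                  scales = pm$scales, u0 = pm$u_ed))
  expect_identical(res$ef, res2$ef)
})

test_that("band mechanics: systolic tension for active, diastolic restraint for passive", {
  pm <- small_patient()
  band_stretch <- function(res, b, w) {
    i <- if (w == 0) res$begin_ejection else res$begin_filling
    u <- res$anchors[[as.character(i)]]$u
    x <- pm$mesh$nodes + u
    L0 <- if (b$passive) b$L0_dia else (1 - w) * b$L0_dia + w * b$L0_sys
    sqrt(sum((x[b$node_a, ] - x[b$node_b, ])^2)) / L0
  }
  active <- make_bands("A", pm$mesh, pm$u_ed, pm$u_bf, ratio = 0.2,
                       materials = pm$materials)
  res_a <- simulate_cycle(vb_model(pm$mesh, pm$materials, pm$pressures,
                                   active, scales = pm$scales, u0 = pm$u_ed))
  lam_sys <- band_stretch(res_a, active[[1]], 1)
  lam_dia <- band_stretch(res_a, active[[1]], 0)
  expect_gt(lam_sys, 1)          # taut at peak systole
  expect_gt(lam_sys, lam_dia)    # systolic stress exceeds diastolic
  passive <- make_bands("A", pm$mesh, pm$u_ed, pm$u_bf, ratio = 0,
                        materials = pm$materials)
  res_p <- simulate_cycle(vb_model(pm$mesh, pm$materials, pm$pressures,
                                   passive, scales = pm$scales, u0 = pm$u_ed))
  expect_gt(band_stretch(res_p, passive[[1]], 0), 1)  # resists dilation
  # the passive band reduces end-diastolic volume
  base <- simulate_cycle(vb_model(pm$mesh, pm$materials, pm$pressures,
                                  scales = pm$scales, u0 = pm$u_ed))
  expect_lt(res_p$edv, base$edv)
  # the active band leaves EDV within 1% and reduces ESV
  expect_equal(res_a$edv, base$edv, tolerance = 0.01 * base$edv)
  expect_lt(res_a$esv, base$esv)
})

test_that("surface stress sampling covers 100 points per slice", {
  pm <- small_patient()
  mp <- material_matrix(pm$mesh, pm$materials, 0, pm$scales)
  fl <- ventriband:::fe_fields(pm$mesh$nodes, pm$mesh$elems, pm$u_ed, mp,
                               pm$mesh$fiber)
  sm <- sample_surface_stress(pm$mesh, pm$u_ed, fl$stress, n_per_slice = 100)
  expect_equal(nrow(sm), 100 * pm$mesh$n_slices)
  # uniform tensor field samples to a constant
  uniform <- matrix(rep(c(5, 5, 5, 0, 0, 0), each = nrow(pm$mesh$elems)),
                    ncol = 6)
  su <- sample_surface_stress(pm$mesh, pm$u_ed, uniform, n_per_slice = 50)
  expect_true(all(abs(su$value - 5) < 1e-12))
  # sampling density robustness: the field is piecewise constant per
  # element, so halving the density changes the overall mean only through
  # segment-boundary quantization
  s2 <- sample_surface_stress(pm$mesh, pm$u_ed, fl$stress, n_per_slice = 50)
  expect_equal(mean(s2$value), mean(sm$value),
               tolerance = 0.1 * abs(mean(sm$value)))
})
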