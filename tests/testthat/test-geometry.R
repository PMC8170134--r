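# Synthetic contour stacks, pressure schedules and IO.

test_that("sphere-limit LV cavity matches the closed form", {
  gp <- geom_params(lv_inner_radius = 30, lv_length = 30, lv_wall = 5,
                    include_rv = FALSE, apex_frac = 0.999, base_frac = 0.999)
  st <- generate_contour_stack(gp, n_slices = 200, n_theta = 100)
  expect_equal(lv_cavity_volume(st), 4 / 3 * pi * 27,
               tolerance = 0.005 * 4 / 3 * pi * 27)
})

test_that("RV cavity can be sized to a target volume", {
  st <- generate_contour_stack(n_slices = 8, n_theta = 64,
                               rv_volume_target = 204.17)
  expect_equal(rv_cavity_volume(st), 204.17, tolerance = 0.02 * 204.17)
  expect_error(generate_contour_stack(n_slices = 2), "3 slices")
  expect_error(generate_contour_stack(rv_volume_target = -5), "positive")
  expect_error(geom_params(lv_wall = -1), "positive")
})

test_that("generated stacks satisfy the contour invariants", {
  st <- generate_contour_stack(n_slices = 6, n_theta = 80)
  expect_true(validate_contour_stack(st, check_simple = TRUE))
  z <- vapply(st$slices, `[[`, numeric(1), "z")
  expect_true(all(diff(z) > 0))
})

test_that("Simpson volume of the stack converges under slice refinement", {
  gp <- geom_params(include_rv = FALSE)
  v <- vapply(c(10, 20, 40, 80), function(n)
    lv_cavity_volume(generate_contour_stack(gp, n_slices = n, n_theta = 64)),
    numeric(1))
  # errors relative to the finest resolution shrink monotonically
  err <- abs(v[1:3] - v[4])
  expect_true(all(diff(err) < 0))
})

test_that("end-systolic stack conserves wall volume and scales the cavity", {
  gp <- geom_params()
  ed <- generate_contour_stack(gp, n_slices = 8, n_theta = 64, phase = "ED")
  es <- generate_contour_stack(gp, n_slices = 8, n_theta = 64, phase = "ES",
                               esv_edv_ratio = 0.62)
  expect_equal(rv_cavity_volume(es) / rv_cavity_volume(ed), 0.62,
               tolerance = 1e-6)
  expect_equal(wall_volume(es), wall_volume(ed),
               tolerance = 1e-3 * wall_volume(ed))
})

test_that("pressure schedule has the documented anchors and units", {
  ps <- generate_pressure_schedule(31.4, 3, n_points = 30)
  expect_length(ps$times, 30)
  expect_equal(max(ps$p_rv), 31.4 * 0.133322, tolerance = 1e-9)
  expect_equal(ps$p_rv[1], max(ps$p_rv))                     # BE at peak
  expect_equal(ps$p_rv[ps$begin_filling], min(ps$p_rv))      # BF at minimum
  # periodic endpoints: t = 0 and t = 1 give the same pressure
  expect_equal(ps$p_rv[1], ps$p_rv[30], tolerance = 1e-12)
  expect_true(all(ps$p_rv >= 0) && all(ps$p_lv >= 0))
  # near-degenerate amplitude
  eps <- 1e-6
  ps2 <- generate_pressure_schedule(3 + eps, 3)
  expect_lt(diff(range(ps2$p_rv)), 2 * eps * 0.133322)
  expect_error(generate_pressure_schedule(3, 5), "p_max > p_min")
})

test_that("contour stack CSV and JSON round trips are bit-exact", {
  st <- generate_contour_stack(n_slices = 5, n_theta = 40)
  csv <- tempfile(fileext = ".csv")
  write_contour_csv(st, csv)
  st2 <- read_contour_csv(csv)
  for (i in seq_along(st$slices)) {
    expect_identical(st2$slices[[i]]$lv_inner[, 1], st$slices[[i]]$lv_inner[, 1])
    expect_identical(st2$slices[[i]]$rv_outer[, 2], st$slices[[i]]$rv_outer[, 2])
    expect_identical(st2$slices[[i]]$z, st$slices[[i]]$z)
  }
  js <- tempfile(fileext = ".json")
  write_contour_json(st, js)
  st3 <- read_contour_json(js)
  expect_equal(st3$slices[[3]]$rv_inner, unclass(st$slices[[3]]$rv_inner),
               tolerance = 0)
  # JSON carries the RV meshing loops
  expect_false(is.null(st3$slices[[2]]$rv_loops))
  expect_equal(st3$slices[[2]]$rv_loops$inner_loop,
               unclass(st$slices[[2]]$rv_loops$inner_loop), tolerance = 0)
})

test_that("malformed contour files raise parse errors", {
  bad <- tempfile(fileext = ".csv")
  writeLines(c("slice_id,ring,point_index,x,y", "1,lv_inner,1,0,0"), bad)
  expect_error(read_contour_csv(bad), "missing field")
  bad2 <- tempfile(fileext = ".csv")
  writeLines(c("slice_id,ring,point_index,x,y,z", "1,lv_inner,1,a,0,0"), bad2)
  expect_error(read_contour_csv(bad2), "non-numeric")
  bad3 <- tempfile(fileext = ".json")
  writeLines("{\"slices\": ", bad3)
  expect_error(read_contour_json(bad3), "parse")
})
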