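# Modified Mooney-Rivlin material: invariants, energy, stress, curves.

test_that("invariants of the Cauchy-Green tensor match hand arithmetic", {
  st <- deformation_state(diag(3))
  expect_equal(invariants(st), list(I1 = 3, I2 = 3, I4 = 1))
  # incompressible uniaxial stretch 1.2 along the fiber
  F1 <- diag(c(1.2, 1 / sqrt(1.2), 1 / sqrt(1.2)))
  inv <- invariants(deformation_state(F1, c(1, 0, 0)))
  expect_equal(inv$I1, 1.44 + 2 / 1.2, tolerance = 1e-9)
  expect_equal(inv$I4, 1.44, tolerance = 1e-12)
  # fiber orthogonal to the stretch axis
  inv2 <- invariants(deformation_state(F1, c(0, 1, 0)))
  expect_equal(inv2$I4, 1 / 1.2, tolerance = 1e-12)
  expect_error(deformation_state(diag(c(-1, 1, 1))), "det F")
})

test_that("strain energy matches scalar arithmetic and is zero at identity", {
  p_iso <- material_params(7.64, 0, 2.41, 3.0, 0)
  expect_equal(strain_energy(p_iso, list(I1 = 3, I2 = 3, I4 = 1)), 0)
  w <- strain_energy(p_iso, list(I1 = 3.1, I2 = 3, I4 = 1))
  expect_equal(w, 7.64 * 0.1 + 2.41 * (exp(0.3) - 1), tolerance = 1e-12)
  p_an <- material_params(0, 0, 0, 0, 36.55, 3.0)
  wa <- strain_energy(p_an, list(I1 = 3, I2 = 3, I4 = 1.1))
  expect_equal(wa, 36.55 / 3 * (exp(3 * 0.01) - 1), tolerance = 1e-12)
  # fiber-compression cutoff: no anisotropic energy for I4 < 1
  expect_equal(strain_energy(p_an, list(I1 = 3, I2 = 3, I4 = 0.9)), 0)
})

test_that("energy is non-negative on isochoric states, zero only at identity", {
  mats <- default_materials()
  for (key in names(mats)) {
    p <- mats[[key]]
    for (lam in seq(0.85, 1.5, by = 0.05)) {
      C <- diag(c(lam^2, 1 / lam, 1 / lam))
      I1 <- sum(diag(C))
      inv <- list(I1 = I1, I2 = 0.5 * (I1^2 - sum(C^2)), I4 = lam^2)
      w <- strain_energy(p, inv)
      if (abs(lam - 1) < 1e-12) expect_equal(w, 0)
      else expect_gt(w, 0)
    }
  }
})

test_that("stress is the exact derivative of the total energy", {
  set.seed(11)
  p <- material_params(7.64, 0.5, 2.41, 3.0, 36.55, 3.0)
  for (rep in 1:20) {
    F0 <- diag(3) + matrix(rnorm(9, 0, 0.08), 3, 3)
    if (det(F0) <= 0.2) next
    nf <- rnorm(3); nf <- nf / sqrt(sum(nf^2))
    st <- deformation_state(F0, nf)
    S <- pk2_stress(st, p, bulk_penalty = 100)
    # central differences of W wrt C (symmetric perturbations)
    h <- 1e-6
    C <- st$C
    for (idx in list(c(1, 1), c(2, 2), c(1, 2), c(2, 3))) {
      i <- idx[1]; j <- idx[2]
      dC <- matrix(0, 3, 3); dC[i, j] <- dC[j, i] <- h
      wplus <- w_of_C(C + dC, nf, p, 100)
      wminus <- w_of_C(C - dC, nf, p, 100)
      # dW/dC_ij symmetric pair: S_ij = 2 dW/dC_ij (off-diag carries both)
      fd <- (wplus - wminus) / (2 * h)
      expected <- if (i == j) S[i, j] / 2 else S[i, j]
      expect_equal(fd, expected, tolerance = 1e-5 * max(1, abs(expected)))
    }
  }
})

test_that("Cauchy stress closed forms: identity, incompressible uniaxial band", {
  band <- material_params(900, region = "band")
  expect_equal(cauchy_stress(deformation_state(diag(3)), band),
               matrix(0, 3, 3), tolerance = 1e-12)
  # lateral-traction-free uniaxial stretch 1.2: sigma = 2 c1 (l^2 - 1/l)
  curve <- uniaxial_stress_curve(band, stretch = 1.2)
  expect_equal(curve$stress_kpa, 2 * 900 * (1.44 - 1 / 1.2),
               tolerance = 1e-9)
  expect_equal(curve$stress_kpa, 1092, tolerance = 1e-9)
})

test_that("material frame indifference and isotropy for K1 = 0", {
  set.seed(3)
  p <- material_params(7.64, 0, 2.41, 3.0, 36.55, 3.0)
  F0 <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
  nf <- c(1, 0, 0)
  w0 <- strain_energy(p, invariants(deformation_state(F0, nf)))
  for (i in 1:20) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    wq <- strain_energy(p, invariants(deformation_state(Q %*% F0, nf)))
    expect_equal(wq, w0, tolerance = 1e-12 * max(1, abs(w0)))
  }
  # K1 = 0: energy independent of fiber direction
  piso <- material_params(7.64, 0, 2.41, 3.0, 0)
  for (i in 1:5) {
    n2 <- rnorm(3); n2 <- n2 / sqrt(sum(n2^2))
    expect_equal(strain_energy(piso, invariants(deformation_state(F0, n2))),
                 strain_energy(piso, invariants(deformation_state(F0, nf))))
  }
})

test_that("uniaxial stress-stretch curves have the expected structure", {
  mats <- default_materials()
  lam <- seq(1.0, 1.3, by = 0.02)
  # monotone increasing, fiber curve above cross-fiber for K1 > 0
  myo <- mats[["myo_inner.end_ejection"]]
  cf <- uniaxial_stress_curve(myo, lam, "fiber")
  cc <- uniaxial_stress_curve(myo, lam, "cross_fiber")
  expect_true(all(diff(cf$stress_kpa) > 0))
  expect_true(all(cf$stress_kpa >= cc$stress_kpa - 1e-12))
  # scar is exactly half of patch at every stretch (parameter proportionality)
  sc <- uniaxial_stress_curve(mats[["scar.all"]], lam)
  pa <- uniaxial_stress_curve(mats[["patch.all"]], lam)
  expect_equal(sc$stress_kpa, 0.5 * pa$stress_kpa, tolerance = 1e-12)
  # end-systolic (stiff) myocardium above end-diastolic pointwise on (1, 1.3]
  soft <- uniaxial_stress_curve(mats[["myo_inner.end_filling"]], lam[-1])
  stiff <- uniaxial_stress_curve(myo, lam[-1])
  expect_true(all(stiff$stress_kpa > soft$stress_kpa))
  expect_equal(uniaxial_stress_curve(myo, 1)$stress_kpa, 0, tolerance = 1e-12)
})

test_that("phase interpolation anchors and midpoint behave as documented", {
  mats <- default_materials()
  ed <- mats[["myo_inner.end_filling"]]   # begin-ejection anchor (soft)
  es <- mats[["myo_inner.end_ejection"]]  # begin-filling anchor (stiff)
  expect_equal(phase_interpolate(ed, es, 0)$c1, 2.78)
  expect_equal(phase_interpolate(ed, es, 1)$c1, 7.64)
  expect_equal(phase_interpolate(ed, es, 0.5)$c1, (7.64 + 2.78) / 2)
  # cosine phase weight: anchors and periodicity
  expect_equal(phase_weight(0), 0)
  expect_equal(phase_weight(0.4), 1)
  expect_equal(phase_weight(1), 0)
  expect_equal(phase_weight(0.2), 0.5)
  other <- material_params(1, region = "elsewhere")
  expect_error(phase_interpolate(ed, other, 0.5), "region")
})
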