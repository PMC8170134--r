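# Shared fixtures, built once per test run and cached.

vb_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(vb_cache[[name]])) vb_cache[[name]] <- force(expr)
  vb_cache[[name]]
}

# concentric-circle (annulus / cylinder) contour stack
make_cylinder_stack <- function(n_s = 5, n_t = 36, ri = 20, ro = 30, h = 40) {
  th <- seq(0, 2 * pi, length.out = n_t + 1)[seq_len(n_t)]
  z <- seq(0, h, length.out = n_s)
  slices <- lapply(z, function(zz) list(
    z = zz,
    lv_inner = cbind(ri * cos(th), ri * sin(th)),
    lv_outer = cbind(ro * cos(th), ro * sin(th))))
  structure(list(slices = slices, slice_spacing = diff(z)[1],
                 orientation = c(0, 0, 1), meta = list()),
            class = "contour_stack")
}

# small bi-ventricle mesh with fibers and landmarks (coarse, fast)
small_biventricle <- function() {
  cached("small_bv", {
    st <- generate_contour_stack(n_slices = 5, n_theta = 64)
    m <- build_mesh(st, n_theta_mesh = 12)
    m <- assign_fibers(m)
    add_band_landmarks(m)
  })
}

# coarse calibrated synthetic patient (shared by solver-level tests)
small_patient <- function() {
  cached("small_patient", {
    cfg <- synthetic_cohort("P5")[[1]]
    build_patient_model(cfg, n_slices = 5, n_theta_mesh = 12)
  })
}

# closed-form incompressible plane-strain cylinder inflation:
# inner radius after pressurization with a c1-only Mooney-Rivlin wall
cylinder_oracle_ri <- function(p, ri = 20, ro = 30, c1 = 10) {
  pr <- function(a) integrate(function(R) {
    r2 <- R^2 + a
    2 * c1 * (r2 / R^2 - R^2 / r2) / r2 * R
  }, ri, ro)$value
  a <- uniroot(function(a) pr(a) - p, c(0, 50 * ro^2))$root
  sqrt(ri^2 + a)
}

# brute-force exact signed-rank two-sided p over all 2^n sign assignments
wilcoxon_brute <- function(a, b) {
  d <- (a - b)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_le <- mean(vs <= v + 1e-9)
  p_ge <- mean(vs >= v - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

rodrigues <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) + pracma_cross(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

# energy as a function of C (via its symmetric square root); used by the
# finite-difference stress checks
w_of_C <- function(C, nf, p, kappa) {
  e <- eigen(C, symmetric = TRUE)
  Fh <- e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)
  strain_energy_total(p, deformation_state(Fh, nf), kappa)
}

# reference element volumes via the FE quadrature
element_volumes <- function(mesh) {
  fl <- ventriband:::fe_fields(mesh$nodes, mesh$elems, 0 * mesh$nodes,
                               matrix(1, nrow(mesh$elems), 7),
                               matrix(1, nrow(mesh$elems), 3))
  fl$ref_volume
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
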