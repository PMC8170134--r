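#' Material parameter set for the modified Mooney-Rivlin law
#'
#' Bundles the six constants of the strain-energy density
#' \deqn{W = c_1(I_1-3) + c_2(I_2-3) + D_1[e^{D_2(I_1-3)}-1]
#'         + (K_1/K_2)[e^{K_2(I_4-1)^2}-1]}
#' together with a region tag and cardiac-phase tag. `c1`, `D1`, `K1` are in
#' kPa; `c2` in kPa; `D2`, `K2` dimensionless. `K1 = 0` gives an isotropic
#' material. The anisotropic exponent convention keeps `K2` inside the
#' exponential, consistent with `K2` being dimensionless and of order 3; set
#' `options(ventriband.aniso_k2_inside = FALSE)` to use the literal
#' `exp((I4-1)^2)` form instead.
#'
#' @param c1,c2,D1,D2,K1,K2 Material constants.
#' @param region Region tag (free string, e.g. "myo_inner", "band").
#' @param phase Phase tag: "end_ejection", "end_filling" or "all".
#' @return Object of class `material_params`.
#' @export
material_params <- function(c1, c2 = 0, D1 = 0, D2 = 0, K1 = 0, K2 = 1,
                            region = "generic", phase = "all") {
  vb_stopifnot(c1 >= 0 && D1 >= 0 && K1 >= 0 && D2 >= 0,
               "c1, D1, D2, K1 must be non-negative")
  if (K1 > 0) vb_stopifnot(K2 > 0, "K2 must be positive when K1 > 0")
  structure(list(c1 = c1, c2 = c2, D1 = D1, D2 = D2, K1 = K1, K2 = K2,
                 region = region, phase = phase),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("<material_params %s/%s> c1=%g c2=%g D1=%g D2=%g K1=%g K2=%g (kPa)\n",
              x$region, x$phase, x$c1, x$c2, x$D1, x$D2, x$K1, x$K2))
  invisible(x)
}

aniso_k2_inside <- function() {
  isTRUE(getOption("ventriband.aniso_k2_inside", TRUE))
}

#' Default material catalogue
#'
#' Loads the bundled material-parameter file (patch, scar, band, and the
#' two-layer myocardium sets at the end-ejection and end-filling anchors) as
#' a list of [material_params()] keyed by `region.phase`.
#'
#' @param file Optional path to a CSV with columns
#'   `region, phase, c1, c2, D1, D2, K1, K2`; defaults to the bundled set.
#' @return Named list of `material_params`.
#' @export
default_materials <- function(file = NULL) {
  if (is.null(file)) file <- vb_extdata("materials_default.csv")
  tab <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("region", "phase", "c1", "c2", "D1", "D2", "K1", "K2")
  vb_stopifnot(all(need %in% names(tab)), "material file missing columns")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    material_params(r$c1, r$c2, r$D1, r$D2, r$K1,
                    K2 = if (r$K2 > 0) r$K2 else 1,
                    region = r$region, phase = r$phase)
  })
  names(out) <- paste(tab$region, tab$phase, sep = ".")
  out
}

#' Deformation state from a deformation gradient
#'
#' @param F_mat 3x3 deformation gradient with positive determinant.
#' @param n_f Unit fiber direction in the reference configuration.
#' @return Object of class `deformation_state` with `F`, `C = F^T F`, `n_f`.
#' @export
deformation_state <- function(F_mat, n_f = c(1, 0, 0)) {
  vb_stopifnot(is.matrix(F_mat) && all(dim(F_mat) == c(3, 3)), "F must be 3x3")
  if (det(F_mat) <= 0) stop("det F must be positive", call. = FALSE)
  n_f <- n_f / sqrt(sum(n_f^2))
  structure(list(F = F_mat, C = crossprod(F_mat), n_f = n_f),
            class = "deformation_state")
}

#' Invariants of the right Cauchy-Green tensor
#'
#' I1 = tr C, I2 = (I1^2 - C:C)/2, I4 = n_f^T C n_f (squared fiber stretch).
#'
#' @param state A [deformation_state()].
#' @return Named list `I1`, `I2`, `I4`.
#' @export
invariants <- function(state) {
  C <- state$C
  ev <- eigen(0.5 * (C + t(C)), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("C is not positive definite", call. = FALSE)
  I1 <- sum(diag(C))
  I2 <- 0.5 * (I1^2 - sum(C * C))
  I4 <- as.numeric(t(state$n_f) %*% C %*% state$n_f)
  list(I1 = I1, I2 = I2, I4 = I4)
}

#' Strain-energy density of the modified Mooney-Rivlin model
#'
#' Isotropic part plus exponential fiber term; the fiber term is active only
#' in fiber extension (I4 > 1) — fibers are assumed to bear no compressive
#' load. Energy is zero in the undeformed state.
#'
#' @param params A [material_params()].
#' @param inv Invariants list as from [invariants()], or a
#'   [deformation_state()].
#' @return Energy density in kPa.
#' @export
strain_energy <- function(params, inv) {
  if (inherits(inv, "deformation_state")) inv <- invariants(inv)
  w <- params$c1 * (inv$I1 - 3) + params$c2 * (inv$I2 - 3)
  if (params$D1 > 0) w <- w + params$D1 * (exp(params$D2 * (inv$I1 - 3)) - 1)
  if (params$K1 > 0 && inv$I4 > 1) {
    q <- (inv$I4 - 1)^2
    w <- w + if (aniso_k2_inside()) {
      params$K1 / params$K2 * (exp(params$K2 * q) - 1)
    } else {
      params$K1 / params$K2 * (exp(q) - 1)
    }
  }
  w
}

# hydrostatic compensation constant: the plain-invariant Mooney-Rivlin
# deviatoric stress at the identity is p0 * I; the classical compressible
# form subtracts p0 ln J from W so the reference state is stress-free
mr_p0 <- function(params) 2 * (params$c1 + params$D1 * params$D2) + 4 * params$c2

#' Total strain energy of the penalty-compressible material
#'
#' The invariant form [strain_energy()] plus the volumetric terms used by
#' the finite-element formulation: `-p0 ln J` (so the reference state is
#' stress-free) and the near-incompressibility penalty
#' `kappa/2 (J - 1)^2`.
#'
#' @param params A [material_params()].
#' @param state A [deformation_state()].
#' @param bulk_penalty Penalty modulus kappa (kPa).
#' @return Energy density (kPa).
#' @export
strain_energy_total <- function(params, state, bulk_penalty = 0) {
  J <- det(state$F)
  strain_energy(params, invariants(state)) - mr_p0(params) * log(J) +
    bulk_penalty / 2 * (J - 1)^2
}

# dW/dI1 and dW/dI4 for the modified Mooney-Rivlin law
mr_dW <- function(params, inv) {
  W1 <- params$c1 + if (params$D1 > 0)
    params$D1 * params$D2 * exp(params$D2 * (inv$I1 - 3)) else 0
  W2 <- params$c2
  W4 <- 0
  if (params$K1 > 0 && inv$I4 > 1) {
    q <- inv$I4 - 1
    W4 <- if (aniso_k2_inside()) {
      2 * params$K1 * q * exp(params$K2 * q^2)
    } else {
      2 * params$K1 / params$K2 * q * exp(q^2)
    }
  }
  list(W1 = W1, W2 = W2, W4 = W4)
}

#' Second Piola-Kirchhoff stress (reference configuration)
#'
#' `S = 2 dW/dC` of [strain_energy_total()]: the invariant part, the
#' hydrostatic compensation `-p0 ln J` that makes the reference state
#' stress-free, and (if `bulk_penalty > 0`) the near-incompressibility
#' penalty `kappa/2 (J - 1)^2`.
#'
#' @param state A [deformation_state()].
#' @param params A [material_params()].
#' @param bulk_penalty Penalty modulus kappa (kPa); 0 disables it.
#' @return Symmetric 3x3 matrix (kPa).
#' @export
pk2_stress <- function(state, params, bulk_penalty = 0) {
  inv <- invariants(state)
  d <- mr_dW(params, inv)
  C <- state$C
  I3 <- diag(3)
  S <- 2 * d$W1 * I3 + 2 * d$W2 * (inv$I1 * I3 - C) +
    2 * d$W4 * tcrossprod(state$n_f)
  J <- det(state$F)
  S + (bulk_penalty * (J - 1) * J - mr_p0(params)) * solve(C)
}

#' Cauchy stress of the modified Mooney-Rivlin material
#'
#' Push-forward of the second Piola-Kirchhoff stress:
#' `sigma = (1/J) F S F^T`. Zero at the identity.
#'
#' @inheritParams pk2_stress
#' @return Symmetric 3x3 Cauchy stress (kPa).
#' @export
cauchy_stress <- function(state, params, bulk_penalty = 0) {
  Fm <- state$F
  J <- det(Fm)
  if (J <= 0) stop("det F must be positive", call. = FALSE)
  S <- pk2_stress(state, params, bulk_penalty)
  (Fm %*% S %*% t(Fm)) / J
}

#' Uniaxial incompressible stress-stretch curve
#'
#' Closed-form Cauchy stress under incompressible uniaxial stretch with
#' traction-free lateral faces, either along the fiber direction or
#' perpendicular to it. Along the fiber,
#' `sigma = 2 W1 (l^2 - 1/l) + 2 W2 (l - 1/l^2) + 2 W4 l^2`.
#'
#' @param params A [material_params()].
#' @param stretch Stretch values, within (0.8, 1.6).
#' @param direction `"fiber"` or `"cross_fiber"`.
#' @return Data frame with columns `stretch`, `stress_kpa`.
#' @export
uniaxial_stress_curve <- function(params, stretch = seq(1, 1.3, by = 0.01),
                                  direction = c("fiber", "cross_fiber")) {
  direction <- match.arg(direction)
  vb_stopifnot(all(stretch > 0.8 & stretch < 1.6),
               "stretch range restricted to (0.8, 1.6)")
  stress <- vapply(stretch, function(l) {
    C <- diag(c(l^2, 1 / l, 1 / l))
    I1 <- sum(diag(C))
    if (direction == "fiber") I4 <- l^2 else I4 <- 1 / l
    inv <- list(I1 = I1, I2 = 0.5 * (I1^2 - sum(C^2)), I4 = I4)
    d <- mr_dW(params, inv)
    s <- 2 * d$W1 * (l^2 - 1 / l) + 2 * d$W2 * (l - 1 / l^2)
    if (direction == "fiber") s <- s + 2 * d$W4 * l^2
    s
  }, numeric(1))
  data.frame(stretch = stretch, stress_kpa = stress)
}

#' Interpolate material parameters across the cardiac cycle
#'
#' Smooth periodic cosine blend between the two anchor parameter sets. A
#' blend weight `w = 0` returns `params_a` exactly and `w = 1` returns
#' `params_b`; intermediate weights blend each scalar linearly in `w`.
#'
#' @param params_a,params_b Anchor [material_params()] with matching regions.
#' @param w Blend weight in `[0, 1]` (use [phase_weight()] to map a cycle
#'   phase to the weight).
#' @return A `material_params` with tag `phase = "blended"`.
#' @export
phase_interpolate <- function(params_a, params_b, w) {
  vb_stopifnot(identical(params_a$region, params_b$region),
               "region tags differ")
  vb_stopifnot(w >= 0 && w <= 1, "blend weight outside [0,1]")
  mix <- function(f) (1 - w) * params_a[[f]] + w * params_b[[f]]
  material_params(mix("c1"), mix("c2"), mix("D1"), mix("D2"), mix("K1"),
                  K2 = mix("K2"), region = params_a$region, phase = "blended")
}

#' Cycle-phase blend weight
#'
#' Periodic piecewise half-cosine weight over the cardiac cycle: 0 at the
#' begin-ejection anchor (`t = 0`), 1 at the begin-filling anchor
#' (`t = systole_fraction`), and back to 0 at `t = 1`. The same weight drives
#' the pressure waveform, the phase-dependent material parameters, and the
#' band zero-stress-length schedule, so all three stay mutually in phase.
#'
#' @param t Cycle phase in `[0, 1]` (values outside are wrapped).
#' @param systole_fraction Fraction of the cycle spent in ejection
#'   (default 0.4).
#' @return Weight in `[0, 1]`, vectorized.
#' @export
phase_weight <- function(t, systole_fraction = 0.4) {
  t <- t %% 1
  ifelse(t <= systole_fraction,
         0.5 * (1 - cos(pi * t / systole_fraction)),
         0.5 * (1 + cos(pi * (t - systole_fraction) / (1 - systole_fraction))))
}
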