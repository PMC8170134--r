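# Contracting-band surgical plans.
#
# A band is a tension-only cable spanning the RV cavity from the free wall
# to the septum. Its zero-stress length follows the cardiac cycle: equal to
# the in-vivo length L at the begin-ejection (diastolic) anchor and to
# (1 - r) L at the begin-filling (peak-systole) anchor, where r is the
# active contraction ratio. The band material stiffens in systole
# (end-ejection value) and softens in diastole (end-filling value, the
# active-relaxation state); a passive band keeps the physical (end-ejection)
# stiffness and a constant zero-stress length the whole cycle, which is why
# it resists diastolic expansion.

#' Zero-stress length factor of a band over the cycle
#'
#' Periodic smooth schedule: 1 at the begin-ejection (diastole) anchor,
#' `1 - r` at the begin-filling (peak systole) anchor, cosine-blended in
#' between; identically 1 for a passive band (`r = 0`).
#'
#' @param band A `band_spec` (or any list with `ratio`).
#' @param cycle_phase Phase in `[0, 1]` (0 = begin ejection).
#' @param systole_fraction Ejection fraction of the cycle (default 0.4).
#' @return Length factor in `[1 - r, 1]`.
#' @export
band_zero_stress_schedule <- function(band, cycle_phase,
                                      systole_fraction = 0.4) {
  r <- band$ratio
  if (r < 0 || r > 0.3) stop("contraction ratio outside [0, 0.3]",
                             call. = FALSE)
  if (isTRUE(band$passive)) return(rep(1, length(cycle_phase)))
  1 - r * phase_weight(cycle_phase, systole_fraction)
}

#' Catalogue of the five band-insertion plans
#'
#' Plans are defined by papillary-muscle-anchored stations, represented in
#' the idealized geometry by parameterized axial/angular anchor positions:
#' plan A one band anterior to the mid-PM level, plan B one posterior,
#' plan C = A + B (two bands), plan D one band at the PM base, and
#' plan E = A + B + D (three bands).
#'
#' @return Named list of character vectors of station names.
#' @export
plan_catalog <- function() {
  list(A = "anterior_mid", B = "posterior_mid", C = c("anterior_mid",
                                                      "posterior_mid"),
       D = "pm_base",
       E = c("anterior_mid", "posterior_mid", "pm_base"))
}

band_station <- function(mesh, station) {
  gp <- attr(mesh, "geom") %||% NULL
  n_s <- mesh$n_slices
  meta <- mesh$band_landmarks
  if (is.null(meta))
    stop("mesh lacks papillary-muscle landmark stations", call. = FALSE)
  st <- meta[[station]]
  if (is.null(st)) stop("unknown band station ", station, call. = FALSE)
  st
}

#' Attach landmark stations to a mesh
#'
#' Defines the synthetic analogues of the papillary-muscle anchor stations
#' used by the band plans: angular offsets on the RV free wall at the
#' mid-cavity and basal-third slice levels.
#'
#' @param mesh A `ventricle_mesh` with an RV.
#' @param center_deg Angular position of the crescent mid-line (degrees).
#' @param offset_deg Anterior/posterior angular offset of the mid stations.
#' @return The mesh with a `band_landmarks` field.
#' @export
add_band_landmarks <- function(mesh, center_deg = 0, offset_deg = 35) {
  if (!"RV" %in% names(mesh$grids))
    stop("mesh has no RV; cannot place band landmarks", call. = FALSE)
  mid <- max(2L, as.integer(round(mesh$n_slices / 2)))
  base3 <- min(mesh$n_slices - 1L, as.integer(round(0.75 * mesh$n_slices)))
  mesh$band_landmarks <- list(
    anterior_mid = list(slice = mid, phi = center_deg + offset_deg),
    posterior_mid = list(slice = mid, phi = center_deg - offset_deg),
    pm_base = list(slice = base3, phi = center_deg))
  mesh
}

#' Build band specifications for a surgery plan
#'
#' Selects free-wall and septal endocardial attachment nodes at each of the
#' plan's stations and sizes the band from the calibrated baseline anchors:
#' the in-vivo band length L is the begin-filling (end-systolic, the
#' model-construction state) attachment separation. An active band's
#' zero-stress length relaxes to the end-diastolic separation at the
#' begin-ejection anchor (active relaxation: it does not resist filling)
#' and contracts to `(1 - r) L` at peak systole. A passive band keeps a
#' constant zero-stress length `(1 - pretension)` times the end-diastolic
#' separation: a diastolic restraint that is slack in systole.
#'
#' @param plan Plan id: `"A"`..`"E"`.
#' @param mesh A `ventricle_mesh` with band landmarks
#'   (see [add_band_landmarks()]).
#' @param u_ed,u_bf N x 3 displacements of the calibrated no-band baseline
#'   at the begin-ejection (end-diastolic) and begin-filling (end-systolic)
#'   anchors.
#' @param ratio Active contraction ratio r in `{0, 0.10, 0.15, 0.20}`;
#'   0 means a passive band.
#' @param area Band cross-section (mm^2, default 10).
#' @param materials Material catalogue (for the band stiffness values).
#' @param pretension Passive-band restraint pre-strain relative to the
#'   end-diastolic separation (default 0.10).
#' @return List of `band_spec` objects.
#' @export
make_bands <- function(plan, mesh, u_ed, u_bf = u_ed, ratio = 0.2, area = 10,
                       materials = default_materials(), pretension = 0.10) {
  stations <- plan_catalog()[[plan]]
  if (is.null(stations)) stop("unknown plan ", plan, call. = FALSE)
  if (ratio < 0 || ratio > 0.3)
    stop("contraction ratio outside [0, 0.3]", call. = FALSE)
  if (is.null(mesh$band_landmarks))
    stop("mesh lacks papillary-muscle landmark stations", call. = FALSE)
  x_ed <- mesh$nodes + u_ed
  x_bf <- mesh$nodes + u_bf
  lapply(stations, function(stn) {
    st <- band_station(mesh, stn)
    na <- rv_surface_node(mesh, st$phi, st$slice, "freewall")
    nb <- rv_surface_node(mesh, st$phi, st$slice, "septum")
    chord_ed <- sqrt(sum((x_ed[na, ] - x_ed[nb, ])^2))
    L <- sqrt(sum((x_bf[na, ] - x_bf[nb, ])^2))
    passive <- ratio == 0
    structure(list(plan = plan, station = stn, ratio = ratio,
                   node_a = na, node_b = nb,
                   L = L,
                   L0_dia = if (passive) (1 - pretension) * chord_ed
                            else chord_ed,
                   L0_sys = if (passive) (1 - pretension) * chord_ed
                            else (1 - ratio) * L,
                   area = area, passive = passive,
                   c1_ee = materials[["band.end_ejection"]]$c1,
                   c1_ef = materials[["band.end_filling"]]$c1),
              class = "band_spec")
  })
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec plan %s %s> L = %.1f mm, r = %.0f%%%s\n",
              x$plan, x$station, x$L, 100 * x$ratio,
              if (x$passive) " (passive)" else ""))
  invisible(x)
}

#' Assemble a simulatable model
#'
#' Bundles mesh, materials, calibrated stiffness scales, pressure schedule
#' and bands into the object consumed by [simulate_cycle()].
#'
#' @param mesh A `ventricle_mesh` with fibers.
#' @param materials Material catalogue.
#' @param pressures A `pressure_schedule`.
#' @param bands List of `band_spec` (possibly empty).
#' @param scales Named stiffness scales `c(ED=, ES=)`.
#' @param kappa_factor Volumetric penalty multiplier.
#' @param u0 Optional initial displacement guess for the first cycle step
#'   (e.g. the calibrated baseline end-diastolic state).
#' @param sys Optional prebuilt [fe_system()] with matching band endpoints
#'   (models differing only in contraction ratio can share one).
#' @param freeze_lv Hold the (mechanically uncoupled) LV body at its
#'   reference state and solve the RV alone; used by the battery for band
#'   models, whose LV solution equals the baseline's.
#' @return Object of class `vb_model`.
#' @export
vb_model <- function(mesh, materials = default_materials(), pressures,
                     bands = list(), scales = c(ED = 1, ES = 1),
                     kappa_factor = 1000, u0 = NULL, sys = NULL,
                     freeze_lv = FALSE) {
  band_nodes <- if (length(bands))
    do.call(rbind, lapply(bands, function(b) c(b$node_a, b$node_b)))
  else matrix(integer(0), 0, 2)
  storage.mode(band_nodes) <- "integer"
  if (is.null(sys))
    sys <- fe_system(mesh, band_nodes,
                     freeze_body = if (freeze_lv) "LV" else NULL)
  else vb_stopifnot(identical(unname(as.vector(sys$band_nodes)),
                              unname(as.vector(band_nodes))),
                    "prebuilt system has different band endpoints")
  band_state_fn <- function(sys, w) {
    if (length(bands) == 0) return(empty_bands())
    do.call(rbind, lapply(bands, function(b) {
      if (b$passive) c(b$node_a, b$node_b, b$L0_dia, b$c1_ee, b$area, 1)
      else c(b$node_a, b$node_b, (1 - w) * b$L0_dia + w * b$L0_sys,
             (1 - w) * b$c1_ef + w * b$c1_ee, b$area, 1)
    }))
  }
  structure(list(sys = sys, materials = materials, pressures = pressures,
                 bands = bands, scales = scales,
                 kappa_factor = kappa_factor,
                 band_state_fn = band_state_fn, u0 = u0),
            class = "vb_model")
}
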