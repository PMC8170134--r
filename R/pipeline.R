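# Synthetic-patient construction and the surgery-plan battery.

#' Synthetic patient presets
#'
#' Seven presets whose RV volumes, EF and peak RV pressure mirror the
#' magnitudes of the reference cohort; the geometry itself is the idealized
#' crescent-around-ellipsoid bi-ventricle, so per-patient EF values are not
#' expected to reproduce any real patient.
#'
#' @param ids Which presets to return (default the three-patient desk-scale
#'   cohort spanning small/large RVs and low/high EF).
#' @return List of patient configuration lists.
#' @export
synthetic_cohort <- function(ids = c("P1", "P5", "P6")) {
  tab <- load_reference_table("cohort")
  lapply(ids, function(id) {
    row <- tab[tab$patient == id, ]
    if (nrow(row) != 1) stop("unknown preset ", id, call. = FALSE)
    list(patient = id, edv_ml = row$rv_edv_ml, esv_ml = row$rv_esv_ml,
         p_max_mmHg = row$p_max_mmHg)
  })
}

#' Build and calibrate one synthetic patient model
#'
#' Generates the end-diastolic geometry sized to the target RV EDV, derives
#' the end-systolic (in-vivo, begin-filling) stack by mass-conserving
#' contour shrinking, estimates the zero-load geometry by preshrink, meshes
#' it, and calibrates the per-phase myocardial stiffness scales so the
#' pressurized RV volumes match the in-vivo EDV/ESV within the calibration
#' tolerance.
#'
#' @param cfg Patient configuration (see [synthetic_cohort()]).
#' @param n_slices,n_theta_mesh Mesh resolution (coarse defaults solve a
#'   full 21-model battery in minutes).
#' @param n_points Time samples per cycle (default 30).
#' @param calibrate Set `FALSE` to skip calibration (scales = 1).
#' @param tolerance Calibration tolerance (default 0.002).
#' @param ... Passed to [geom_params()] overrides.
#' @return List: `mesh`, `materials`, `scales`, `calibration`, `pressures`,
#'   `invivo_es` stack, `targets`, `patient`.
#' @export
build_patient_model <- function(cfg, n_slices = 6, n_theta_mesh = 14,
                                n_points = 30, calibrate = TRUE,
                                tolerance = 0.002, ...) {
  size <- (cfg$edv_ml / 300)^(1 / 3)
  gp <- geom_params(lv_inner_radius = 22 * size, lv_length = 48 * size,
                    lv_wall = 10 * size, rv_wall = 5 * size,
                    rv_septal_wall = 4 * size, rv_bulge = 40 * size, ...)
  ed <- generate_contour_stack(gp, n_slices = n_slices, n_theta = 96,
                               phase = "ED", rv_volume_target = cfg$edv_ml)
  gp_sized <- ed$meta$geom
  es <- generate_contour_stack(gp_sized, n_slices = n_slices, n_theta = 96,
                               phase = "ES",
                               esv_edv_ratio = cfg$esv_ml / cfg$edv_ml)
  zero_load <- preshrink_contours(es, shrink_spec(0.03, 0.03))
  mesh <- build_mesh(zero_load, n_theta_mesh = n_theta_mesh)
  mesh <- assign_fibers(mesh)
  mesh <- add_band_landmarks(mesh)
  mats <- default_materials()
  pressures <- generate_pressure_schedule(cfg$p_max_mmHg, n_points = n_points)
  targets <- c(edv = rv_cavity_volume(ed), esv = rv_cavity_volume(es))
  scales <- c(ED = 1, ES = 1)
  calib <- NULL
  if (calibrate) {
    vf <- make_volume_fn(mesh, mats, pressures)
    calib <- calibrate_materials(vf, targets["edv"], targets["esv"],
                                 tolerance = tolerance)
    scales <- calib$scales
  }
  # anchor states of the calibrated baseline: they define the band
  # attachment separations and warm-start the cycle simulations
  sys0 <- fe_system(mesh)
  i_ed <- pressures$begin_ejection
  i_bf <- pressures$begin_filling
  u_ed <- solve_equilibrium(sys0, material_matrix(mesh, mats, 0, scales),
                            pressures$p_rv[i_ed], pressures$p_lv[i_ed])$u
  u_bf <- solve_equilibrium(sys0, material_matrix(mesh, mats, 1, scales),
                            pressures$p_rv[i_bf], pressures$p_lv[i_bf])$u
  list(patient = cfg$patient, mesh = mesh, materials = mats,
       scales = scales, calibration = calib, pressures = pressures,
       invivo_es = es, targets = targets, u_ed = u_ed, u_bf = u_bf,
       cfg = cfg)
}

#' Pressurized-RV-volume function used by the calibration
#'
#' Returns a closure `(scale, anchor)` that solves the static equilibrium at
#' the requested anchor (ED: peak pressures with the begin-ejection
#' parameter set; ES: minimum pressures with the begin-filling set), with
#' the myocardial (c1, D1, K1) multiplied by `scale`, and reports the RV
#' cavity volume (ml). Solutions are warm-started across calls.
#'
#' @param mesh,mats,pressures Model ingredients.
#' @param kappa_factor Volumetric penalty multiplier.
#' @return Function `(scale, anchor)` -> volume in ml.
#' @export
make_volume_fn <- function(mesh, mats, pressures, kappa_factor = 1000) {
  sys <- fe_system(mesh)
  cache <- new.env()
  function(scale, anchor = c("ED", "ES")) {
    anchor <- match.arg(anchor)
    w <- if (anchor == "ED") 0 else 1
    i <- if (anchor == "ED") pressures$begin_ejection else pressures$begin_filling
    scales <- if (anchor == "ED") c(ED = scale, ES = 1) else c(ED = 1, ES = scale)
    matpar <- material_matrix(mesh, mats, w, scales, kappa_factor)
    u0 <- cache[[anchor]]
    sol <- tryCatch(
      solve_equilibrium(sys, matpar, pressures$p_rv[i], pressures$p_lv[i],
                        u0 = u0),
      error = function(e) NULL)
    if (is.null(sol)) {
      sol <- solve_equilibrium(sys, matpar, pressures$p_rv[i],
                               pressures$p_lv[i])
    }
    cache[[anchor]] <- sol$u
    cavity_volume(mesh, "RV", sol$u)
  }
}

#' Enumerate the model battery for one or more patients
#'
#' Full factorial of plans and contraction ratios plus the no-band baseline,
#' named by the standard convention (plan prefixes A, P, AP, B, APB and the
#' percent-contraction suffix, e.g. `APB020`).
#'
#' @param patients Character vector of patient ids.
#' @param plans Plan ids (subset of A-E).
#' @param ratios Contraction ratios (0 = passive band).
#' @return Data frame: `patient`, `model`, `plan`, `ratio`.
#' @export
enumerate_models <- function(patients, plans = c("A", "B", "C", "D", "E"),
                             ratios = c(0, 0.10, 0.15, 0.20)) {
  if (length(plans) && !all(plans %in% c("A", "B", "C", "D", "E")))
    stop("unknown plan id", call. = FALSE)
  prefix <- c(A = "A", B = "P", C = "AP", D = "B", E = "APB")
  rows <- list()
  for (p in patients) {
    rows[[length(rows) + 1]] <- data.frame(
      patient = p, model = "Baseline", plan = NA_character_, ratio = NA_real_)
    for (pl in plans) for (r in ratios) {
      rows[[length(rows) + 1]] <- data.frame(
        patient = p, model = sprintf("%s%03.0f", prefix[pl], 100 * r),
        plan = pl, ratio = r)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyDuplicated(paste(out$patient, out$model)))
    stop("duplicate model names", call. = FALSE)
  out
}

#' Run a battery of band-insertion models
#'
#' For each patient: builds and calibrates the baseline model once, then
#' simulates the no-band baseline and every plan/ratio combination through
#' the cardiac cycle, reporting RV volumes, surface stress/strain and EF at
#' the begin-filling and begin-ejection anchors, and the EF improvement over
#' the same patient's baseline. Individual model failures are recorded, not
#' fatal. Results are deterministic and independent of `workers`.
#'
#' @param cohort List of patient configurations ([synthetic_cohort()]).
#' @param plans,ratios Battery factors.
#' @param n_slices,n_theta_mesh,n_points Resolution settings passed to
#'   [build_patient_model()].
#' @param workers Number of parallel worker processes (throughput only).
#' @param verbose Print per-model progress.
#' @return Object of class `battery_result`: `results` data frame and
#'   `patients` (the built models).
#' @export
run_battery <- function(cohort, plans = c("A", "B", "C", "D", "E"),
                        ratios = c(0, 0.10, 0.15, 0.20),
                        n_slices = 6, n_theta_mesh = 14, n_points = 30,
                        workers = 1, verbose = FALSE) {
  run_patient <- function(cfg) {
    pm <- build_patient_model(cfg, n_slices = n_slices,
                              n_theta_mesh = n_theta_mesh,
                              n_points = n_points)
    configs <- enumerate_models(cfg$patient, plans, ratios)
    base_ef <- NA_real_
    rows <- list()
    sys_cache <- list()  # plans share band endpoints across ratios
    for (i in seq_len(nrow(configs))) {
      cfgi <- configs[i, ]
      if (verbose) message(cfg$patient, " ", cfgi$model)
      res <- tryCatch({
        bands <- if (is.na(cfgi$plan)) list() else
          make_bands(cfgi$plan, pm$mesh, pm$u_ed, pm$u_bf,
                     ratio = cfgi$ratio, materials = pm$materials)
        key <- if (is.na(cfgi$plan)) "baseline" else cfgi$plan
        mod <- vb_model(pm$mesh, pm$materials, pm$pressures, bands,
                        scales = pm$scales, u0 = pm$u_ed,
                        sys = sys_cache[[key]],
                        freeze_lv = !is.na(cfgi$plan))
        sys_cache[[key]] <- mod$sys
        simulate_cycle(mod)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rows[[i]] <- data.frame(
          patient = cfg$patient, model = cfgi$model, plan = cfgi$plan,
          ratio = cfgi$ratio, bf_vol_ml = NA, bf_stress_kpa = NA,
          bf_strain = NA, be_vol_ml = NA, be_stress_kpa = NA, be_strain = NA,
          ef_pct = NA, delta_ef_pct = NA, cycles = NA,
          error = conditionMessage(res))
        next
      }
      if (cfgi$model == "Baseline") base_ef <- res$ef
      rows[[i]] <- data.frame(
        patient = cfg$patient, model = cfgi$model, plan = cfgi$plan,
        ratio = cfgi$ratio,
        bf_vol_ml = res$esv, bf_stress_kpa = res$stress_bf,
        bf_strain = res$strain_bf,
        be_vol_ml = res$edv, be_stress_kpa = res$stress_be,
        be_strain = res$strain_be,
        ef_pct = res$ef,
        delta_ef_pct = if (cfgi$model == "Baseline") 0 else res$ef - base_ef,
        cycles = res$cycles, error = NA_character_)
    }
    list(rows = do.call(rbind, rows), model = pm)
  }
  out <- if (workers > 1 && requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(cohort, run_patient, mc.cores = workers)
  } else {
    lapply(cohort, run_patient)
  }
  results <- do.call(rbind, lapply(out, `[[`, "rows"))
  rownames(results) <- NULL
  if (all(is.na(results$ef_pct)))
    stop("all battery models failed", call. = FALSE)
  structure(list(results = results,
                 patients = lapply(out, `[[`, "model")),
            class = "battery_result")
}

#' @export
print.battery_result <- function(x, ...) {
  cat(sprintf("<battery_result> %d models, %d patients, %d failed\n",
              nrow(x$results), length(x$patients),
              sum(!is.na(x$results$error))))
  invisible(x)
}

#' Summarize a battery as cohort means
#'
#' Mean and sample SD of each reported quantity per model name, mirroring
#' the cohort-summary table layout.
#'
#' @param battery A `battery_result` (or its `results` data frame).
#' @return Data frame keyed by model name.
#' @export
summarize_battery <- function(battery) {
  res <- if (inherits(battery, "battery_result")) battery$results else battery
  res <- res[is.na(res$error), ]
  cols <- c("bf_vol_ml", "bf_stress_kpa", "bf_strain", "be_vol_ml",
            "be_stress_kpa", "be_strain", "ef_pct", "delta_ef_pct")
  out <- lapply(split(res, res$model), function(d) {
    row <- data.frame(model = d$model[1], n = nrow(d))
    for (cc in cols) {
      row[[paste0(cc, "_mean")]] <- mean(d[[cc]])
      row[[paste0(cc, "_sd")]] <- if (nrow(d) > 1) sd(d[[cc]]) else NA_real_
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write battery results as CSV
#'
#' @param battery A `battery_result`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
export_battery <- function(battery, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(battery$results, file.path(dir, "results.csv"), row.names = FALSE)
  write.csv(summarize_battery(battery), file.path(dir, "summary.csv"),
            row.names = FALSE)
  invisible(dir)
}
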