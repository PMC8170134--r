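# Idealized CMR-like bi-ventricular contour geometry.
#
# The left ventricle is a truncated ellipsoid of revolution (two nested
# surfaces: endocardium and epicardium). The right ventricle is a crescent
# wrapped around the LV: on each short-axis slice its cavity lies between a
# septal circular arc (radius tracking the LV epicardium) and a free-wall
# bulge arc; the RV wall is the closed ring of tissue around that cavity.
# Slices are ordered apex -> base along +z, lengths in mm, volumes in ml.

polygon_area <- function(p) {
  # shoelace, absolute value
  x <- p[, 1]; y <- p[, 2]
  0.5 * abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y))
}

polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

is_simple_polygon <- function(p) {
  n <- nrow(p)
  if (n < 3) return(FALSE)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    js <- seq(i + 2, jmax)
    for (j in js) {
      jn <- if (j == n) 1 else j + 1
      if (segments_intersect(p[i, ], p[i + 1, ], p[j, ], p[jn, ])) return(FALSE)
    }
  }
  TRUE
}

point_in_polygon <- function(pt, poly) {
  # ray casting
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > pt[2]) != (yj > pt[2])) {
      xint <- (xj - xi) * (pt[2] - yi) / (yj - yi) + xi
      if (pt[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Geometry parameters for the idealized bi-ventricle
#'
#' @param lv_inner_radius LV endocardial equatorial radius (mm).
#' @param lv_length LV endocardial long semi-axis (mm).
#' @param lv_wall LV wall thickness (mm).
#' @param rv_span Angular extent of the RV crescent (degrees).
#' @param rv_center Angular position of the crescent mid-line (degrees).
#' @param rv_bulge Maximum RV cavity thickness at the equator (mm).
#' @param rv_wall RV free-wall thickness (mm).
#' @param rv_septal_wall Septal RV wall thickness (mm).
#' @param apex_frac,base_frac Axial truncation: slices cover
#'   `z` from `-apex_frac * lv_length` to `+base_frac * lv_length`.
#' @param include_lv,include_rv Toggle either ventricle (for single-cavity
#'   verification geometries).
#' @return List of class `geom_params`.
#' @export
geom_params <- function(lv_inner_radius = 22, lv_length = 48, lv_wall = 10,
                        rv_span = 165, rv_center = 0, rv_bulge = 40,
                        rv_wall = 5, rv_septal_wall = 4,
                        apex_frac = 0.9, base_frac = 0.5,
                        include_lv = TRUE, include_rv = TRUE) {
  p <- as.list(environment())
  vb_stopifnot(lv_inner_radius > 0 && lv_length > 0 && lv_wall > 0,
               "LV axes and wall thickness must be positive")
  vb_stopifnot(rv_bulge > 0 && rv_wall > 0 && rv_septal_wall > 0,
               "RV dimensions must be positive")
  vb_stopifnot(rv_span > 30 && rv_span < 300, "rv_span out of range")
  structure(p, class = "geom_params")
}

# crescent cross-section at height z; returns matched boundary loops
crescent_slice <- function(gp, z, n_half) {
  cL <- gp$lv_length + gp$lv_wall          # epicardial long semi-axis
  aL <- gp$lv_inner_radius + gp$lv_wall    # epicardial equatorial radius
  s_out <- sqrt(max(1 - (z / cL)^2, 0.0025))
  r_epi <- aL * s_out
  r_sept <- r_epi + gp$rv_septal_wall
  taper <- sqrt(max(1 - (z / cL)^2, 0.01))
  H <- gp$rv_bulge * taper
  phi0 <- (gp$rv_center - gp$rv_span / 2) * pi / 180
  phi1 <- (gp$rv_center + gp$rv_span / 2) * pi / 180
  phi <- seq(phi0, phi1, length.out = n_half)
  h <- H * sin(pi * (phi - phi0) / (phi1 - phi0))
  # k-loop around the wall: free-wall half (phi ascending), septal half back
  fw_in  <- cbind((r_sept + h) * cos(phi), (r_sept + h) * sin(phi))
  fw_out <- cbind((r_sept + h + gp$rv_wall) * cos(phi),
                  (r_sept + h + gp$rv_wall) * sin(phi))
  sp_phi <- rev(phi)
  sp_in  <- cbind(r_sept * cos(sp_phi), r_sept * sin(sp_phi))
  sp_out <- cbind(r_epi * cos(sp_phi), r_epi * sin(sp_phi))
  # wrap the outer boundary slightly past the horns so the cavity polygon is
  # strictly inside it (the horn cap wall wraps around the cavity tip)
  dphi <- 0.5 * (phi1 - phi0) / (n_half - 1)
  rot <- function(p, a) c(cos(a) * p[1] - sin(a) * p[2],
                          sin(a) * p[1] + cos(a) * p[2])
  fw_out[1, ] <- rot(fw_out[1, ], -dphi)
  fw_out[n_half, ] <- rot(fw_out[n_half, ], dphi)
  sp_out[1, ] <- rot(sp_out[1, ], dphi)
  sp_out[n_half, ] <- rot(sp_out[n_half, ], -dphi)
  inner_loop <- rbind(fw_in, sp_in)
  outer_loop <- rbind(fw_out, sp_out)
  # cavity polygon: free-wall arc then septal arc, horn duplicates dropped
  cavity <- rbind(fw_in[-n_half, , drop = FALSE], sp_in[-n_half, , drop = FALSE])
  list(inner_loop = inner_loop, outer_loop = outer_loop,
       cavity = cavity, outer_poly = outer_loop,
       n_half = n_half, phi = phi, r_sept = r_sept)
}

#' Generate an idealized bi-ventricular contour stack
#'
#' Builds stacked short-axis inner/outer contours for a truncated-ellipsoid
#' LV and a crescent RV at the requested cardiac phase. The end-systolic
#' stack is derived from the end-diastolic one by contour shrinking with
#' wall-volume conservation, so wall mass is identical at the two phases.
#'
#' @param gp A [geom_params()].
#' @param n_slices Number of short-axis slices (>= 3, default 10).
#' @param n_theta Contour points per closed contour (default 100).
#' @param phase `"ED"` or `"ES"`.
#' @param esv_edv_ratio Cavity volume ratio ES/ED used to derive the ES
#'   stack (default 0.62).
#' @param rv_volume_target Optional RV cavity volume (ml) at the requested
#'   phase; the crescent bulge is rescaled to match it within 0.1%.
#' @return Object of class `contour_stack`.
#' @export
generate_contour_stack <- function(gp = geom_params(), n_slices = 10,
                                   n_theta = 100, phase = c("ED", "ES"),
                                   esv_edv_ratio = 0.62,
                                   rv_volume_target = NULL) {
  phase <- match.arg(phase)
  if (n_slices < 3) stop("need at least 3 slices", call. = FALSE)
  vb_stopifnot(n_theta >= 8, "n_theta too small")
  if (!is.null(rv_volume_target)) {
    vb_stopifnot(isTRUE(gp$include_rv), "RV volume target without RV")
    if (rv_volume_target <= 0) stop("RV volume target must be positive",
                                    call. = FALSE)
    f <- function(m) {
      gp2 <- gp; gp2$rv_bulge <- gp$rv_bulge * m
      st <- generate_contour_stack(gp2, n_slices, n_theta, phase,
                                   esv_edv_ratio)
      rv_cavity_volume(st) - rv_volume_target
    }
    m <- uniroot(f, c(0.05, 25), tol = 1e-7)$root
    gp$rv_bulge <- gp$rv_bulge * m
  }
  cI <- gp$lv_length; aI <- gp$lv_inner_radius
  cO <- cI + gp$lv_wall
  z <- seq(-gp$apex_frac * cI, gp$base_frac * cI, length.out = n_slices)
  n_half <- max(6L, as.integer(ceiling((n_theta + 2) / 2)))
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[seq_len(n_theta)]
  slices <- lapply(z, function(zz) {
    sl <- list(z = zz)
    if (gp$include_lv) {
      ri <- aI * sqrt(max(1 - (zz / cI)^2, 1e-4))
      ro <- (aI + gp$lv_wall) * sqrt(max(1 - (zz / cO)^2, 1e-4))
      sl$lv_inner <- cbind(ri * cos(theta), ri * sin(theta))
      sl$lv_outer <- cbind(ro * cos(theta), ro * sin(theta))
    }
    if (gp$include_rv) {
      cr <- crescent_slice(gp, zz, n_half)
      sl$rv_inner <- cr$cavity
      sl$rv_outer <- cr$outer_poly
      sl$rv_loops <- cr[c("inner_loop", "outer_loop", "n_half", "phi", "r_sept")]
    }
    sl
  })
  stack <- structure(list(
    slices = slices,
    slice_spacing = diff(z)[1],
    orientation = c(0, 0, 1),
    meta = list(geom = gp, phase = "ED", n_half = n_half, n_theta = n_theta)
  ), class = "contour_stack")
  if (phase == "ES") {
    s_lin <- esv_edv_ratio^(1 / 3)
    stack <- preshrink_contours(
      stack, shrink_spec(inner_rate = 1 - s_lin, long_axis_rate = 1 - s_lin,
                         rate_cap = 0.5))
    stack$meta$phase <- "ES"
  }
  stack
}

#' @export
print.contour_stack <- function(x, ...) {
  ns <- length(x$slices)
  cat(sprintf("<contour_stack> %d slices, spacing %.2f mm", ns,
              x$slice_spacing))
  if (!is.null(x$slices[[1]]$lv_inner))
    cat(sprintf(", LV cavity %.1f ml", lv_cavity_volume(x)))
  if (!is.null(x$slices[[1]]$rv_inner))
    cat(sprintf(", RV cavity %.1f ml", rv_cavity_volume(x)))
  cat("\n")
  invisible(x)
}

stack_z <- function(stack) vapply(stack$slices, `[[`, numeric(1), "z")

cavity_areas <- function(stack, ring) {
  vapply(stack$slices, function(sl) {
    p <- sl[[ring]]
    if (is.null(p)) 0 else polygon_area(p)
  }, numeric(1))
}

#' Simpson cavity volumes of a contour stack
#'
#' @param stack A `contour_stack`.
#' @return Volume in ml.
#' @export
rv_cavity_volume <- function(stack)
  simpson_volume(cavity_areas(stack, "rv_inner"), stack_z(stack))

#' @rdname rv_cavity_volume
#' @export
lv_cavity_volume <- function(stack)
  simpson_volume(cavity_areas(stack, "lv_inner"), stack_z(stack))

#' Validate contour stack invariants
#'
#' Checks slice count, strictly increasing z, simple polygons, and inner
#' contours lying strictly inside their outer contours.
#'
#' @param stack A `contour_stack`.
#' @param check_simple Also run the O(n^2) polygon self-intersection check.
#' @return Invisibly `TRUE`; stops with a message otherwise.
#' @export
validate_contour_stack <- function(stack, check_simple = FALSE) {
  vb_stopifnot(inherits(stack, "contour_stack"), "not a contour_stack")
  z <- stack_z(stack)
  if (length(z) < 3) stop("need at least 3 slices", call. = FALSE)
  if (any(diff(z) <= 0)) stop("z positions must be strictly increasing",
                              call. = FALSE)
  for (i in seq_along(stack$slices)) {
    sl <- stack$slices[[i]]
    for (pair in list(c("lv_inner", "lv_outer"), c("rv_inner", "rv_outer"))) {
      pin <- sl[[pair[1]]]; pout <- sl[[pair[2]]]
      if (is.null(pin)) next
      if (check_simple &&
          (!is_simple_polygon(pin) || !is_simple_polygon(pout)))
        stop("self-intersecting contour on slice ", i, call. = FALSE)
      ok <- all(vapply(seq_len(nrow(pin)), function(j)
        point_in_polygon(pin[j, ], pout), logical(1)))
      if (!ok) stop("inner contour outside outer contour on slice ", i,
                    call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Two-phase cavity pressure schedule
#'
#' Smooth periodic waveform over one cardiac cycle: maximum pressure at the
#' begin-ejection anchor (`t = 0`), half-cosine decay to the minimum at begin
#' filling (`t = systole_fraction`), half-cosine recovery over filling.
#' Pressures are supplied in mmHg and stored in kPa
#' (1 mmHg = 0.133322 kPa).
#'
#' @param p_rv_max,p_rv_min RV pressure extrema (mmHg), `p_rv_max > p_rv_min >= 0`.
#' @param p_lv_max,p_lv_min LV pressure extrema (mmHg).
#' @param n_points Number of time samples over the cycle (default 30);
#'   `t = 0` and `t = 1` map to the same state.
#' @param systole_fraction Ejection fraction of the cycle (default 0.4).
#' @return Object of class `pressure_schedule` with fields `times`, `p_rv`,
#'   `p_lv` (kPa), `begin_ejection`, `begin_filling` (indices).
#' @export
generate_pressure_schedule <- function(p_rv_max, p_rv_min = 3,
                                       p_lv_max = 120, p_lv_min = 8,
                                       n_points = 30,
                                       systole_fraction = 0.4) {
  if (!(p_rv_max > p_rv_min) || p_rv_min < 0)
    stop("need p_max > p_min >= 0", call. = FALSE)
  if (!(p_lv_max > p_lv_min) || p_lv_min < 0)
    stop("need p_max > p_min >= 0 for LV", call. = FALSE)
  vb_stopifnot(n_points >= 4, "need at least 4 time points")
  t <- seq(0, 1, length.out = n_points)
  w <- phase_weight(t, systole_fraction)
  kp <- MMHG_TO_KPA
  structure(list(
    times = t,
    p_rv = kp * (p_rv_min + (p_rv_max - p_rv_min) * (1 - w)),
    p_lv = kp * (p_lv_min + (p_lv_max - p_lv_min) * (1 - w)),
    begin_ejection = 1L,
    begin_filling = which.min(abs(t - systole_fraction)),
    systole_fraction = systole_fraction
  ), class = "pressure_schedule")
}

# ---- contour stack IO ----------------------------------------------------

#' Write / read contour stacks (CSV and JSON dialects)
#'
#' The CSV dialect has columns `slice_id, ring, point_index, x, y, z` with
#' full double precision, so a write/read round trip reproduces coordinates
#' bit-exactly. The JSON dialect nests the same data per slice. Meshing
#' metadata for the crescent RV is carried by the JSON dialect only.
#'
#' @param stack A `contour_stack`.
#' @param path Output file path.
#' @return `write_*` return `path` invisibly; `read_*` return the stack.
#' @export
write_contour_csv <- function(stack, path) {
  rows <- list()
  for (i in seq_along(stack$slices)) {
    sl <- stack$slices[[i]]
    for (ring in c("lv_inner", "lv_outer", "rv_inner", "rv_outer")) {
      p <- sl[[ring]]
      if (is.null(p)) next
      rows[[length(rows) + 1]] <- data.frame(
        slice_id = i, ring = ring, point_index = seq_len(nrow(p)),
        x = sprintf("%.17g", p[, 1]), y = sprintf("%.17g", p[, 2]),
        z = sprintf("%.17g", sl$z))
    }
  }
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse contour CSV: ",
                                          conditionMessage(e), call. = FALSE))
  need <- c("slice_id", "ring", "point_index", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("contour CSV missing field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cc in c("x", "y", "z")) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(df[[cc]]))
      stop("contour CSV: non-numeric value in column ", cc, call. = FALSE)
  }
  ids <- sort(unique(df$slice_id))
  slices <- lapply(ids, function(i) {
    sub <- df[df$slice_id == i, ]
    sl <- list(z = sub$z[1])
    for (ring in unique(sub$ring)) {
      r <- sub[sub$ring == ring, ]
      r <- r[order(r$point_index), ]
      sl[[ring]] <- cbind(r$x, r$y)
    }
    sl
  })
  z <- vapply(slices, `[[`, numeric(1), "z")
  structure(list(slices = slices,
                 slice_spacing = if (length(z) > 1) diff(z)[1] else NA_real_,
                 orientation = c(0, 0, 1), meta = list()),
            class = "contour_stack")
}

#' @rdname write_contour_csv
#' @export
write_contour_json <- function(stack, path) {
  # numbers serialized at 17 significant digits so the round trip is
  # bit-exact (strtod recovers the identical double)
  num <- function(x) sprintf("%.17g", x)
  arr <- function(v) paste0("[", paste(num(v), collapse = ","), "]")
  mat <- function(m) paste0("[", paste(apply(m, 1, arr), collapse = ","), "]")
  slice_json <- function(sl) {
    parts <- c(sprintf("\"z\":%s", num(sl$z)))
    for (ring in c("lv_inner", "lv_outer", "rv_inner", "rv_outer"))
      if (!is.null(sl[[ring]]))
        parts <- c(parts, sprintf("\"%s\":%s", ring, mat(sl[[ring]])))
    if (!is.null(sl$rv_loops)) {
      rl <- sl$rv_loops
      parts <- c(parts, sprintf(
        "\"rv_loops\":{\"inner_loop\":%s,\"outer_loop\":%s,\"n_half\":%d,\"phi\":%s,\"r_sept\":%s}",
        mat(rl$inner_loop), mat(rl$outer_loop), as.integer(rl$n_half),
        arr(rl$phi), num(rl$r_sept)))
    }
    paste0("{", paste(parts, collapse = ","), "}")
  }
  json <- paste0(
    "{\"slice_spacing\":", num(stack$slice_spacing),
    ",\"orientation\":", arr(stack$orientation),
    ",\"meta\":{\"n_half\":", if (is.null(stack$meta$n_half)) "null"
    else as.integer(stack$meta$n_half), "}",
    ",\"slices\":[",
    paste(vapply(stack$slices, slice_json, character(1)), collapse = ","),
    "]}")
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse contour JSON: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(obj$slices)) stop("contour JSON: missing 'slices'", call. = FALSE)
  as_mat <- function(rows)
    do.call(rbind, lapply(rows, function(r) unlist(r, use.names = FALSE)))
  slices <- lapply(obj$slices, function(sl) {
    out <- list(z = sl$z)
    for (ring in c("lv_inner", "lv_outer", "rv_inner", "rv_outer"))
      if (!is.null(sl[[ring]])) out[[ring]] <- as_mat(sl[[ring]])
    if (!is.null(sl$rv_loops)) {
      out$rv_loops <- list(
        inner_loop = as_mat(sl$rv_loops$inner_loop),
        outer_loop = as_mat(sl$rv_loops$outer_loop),
        n_half = sl$rv_loops$n_half,
        phi = unlist(sl$rv_loops$phi, use.names = FALSE),
        r_sept = sl$rv_loops$r_sept)
    }
    out
  })
  z <- vapply(slices, `[[`, numeric(1), "z")
  structure(list(slices = slices,
                 slice_spacing = if (length(z) > 1) diff(z)[1] else NA_real_,
                 orientation = c(0, 0, 1),
                 meta = list(n_half = obj$meta$n_half)),
            class = "contour_stack")
}
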