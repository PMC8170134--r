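# Zero-load geometry estimation by contour shrinking, and secant calibration
# of material stiffness to imaging volumes.

#' Shrink specification for zero-load geometry estimation
#'
#' In-vivo contours are shrunk toward the zero-load state: inner contours by
#' `inner_rate` toward their per-slice centroid, the slice spacing by
#' `long_axis_rate`, and the outer contours by a solved factor that keeps the
#' total ventricular wall volume unchanged (conservation of wall mass).
#'
#' @param inner_rate Short-axis shrink fraction for inner contours
#'   (default 0.03; the physiological range is 0.02-0.03).
#' @param long_axis_rate Long-axis shrink fraction (default 0.03).
#' @param scope `"global"` (one outer factor for the whole stack) or
#'   `"per_slice"`.
#' @param rate_cap Upper validity bound on the rates (default 0.1).
#' @return Object of class `shrink_spec`.
#' @export
shrink_spec <- function(inner_rate = 0.03, long_axis_rate = 0.03,
                        scope = c("global", "per_slice"), rate_cap = 0.1) {
  scope <- match.arg(scope)
  vb_stopifnot(inner_rate > -rate_cap && inner_rate < rate_cap,
               "inner_rate outside validity range")
  vb_stopifnot(long_axis_rate > -rate_cap && long_axis_rate < rate_cap,
               "long_axis_rate outside validity range")
  structure(list(inner_rate = inner_rate, long_axis_rate = long_axis_rate,
                 scope = scope), class = "shrink_spec")
}

scale_about <- function(p, center, s) {
  sweep(sweep(p, 2, center, "-") * s, 2, center, "+")
}

#' Total ventricular wall volume of a contour stack
#'
#' Composite-Simpson combination over slices of (outer area - inner area)
#' for every ventricle present, times slice spacing.
#'
#' @param stack A `contour_stack`.
#' @return Wall volume in ml.
#' @export
wall_volume <- function(stack) {
  z <- stack_z(stack)
  if (length(z) < 3) stop("need at least 3 slices", call. = FALSE)
  a <- cavity_areas(stack, "lv_outer") - cavity_areas(stack, "lv_inner") +
    cavity_areas(stack, "rv_outer") - cavity_areas(stack, "rv_inner")
  simpson_volume(a, z)
}

#' Shrink in-vivo contours to an approximate zero-load geometry
#'
#' Inner contours are scaled by `1 - inner_rate` toward their per-slice
#' centroids and slice positions are contracted by `1 - long_axis_rate`
#' about the stack mid-plane. Outer contours are then rescaled (globally or
#' per slice) so the total wall volume is conserved; the conservation
#' equation is quadratic in the outer scale factor and is solved in closed
#' form.
#'
#' @param stack A `contour_stack`.
#' @param spec A [shrink_spec()].
#' @return The shrunk `contour_stack`; attribute `outer_scale` records the
#'   solved outer factor(s).
#' @export
preshrink_contours <- function(stack, spec = shrink_spec()) {
  z <- stack_z(stack)
  if (length(z) < 3) stop("need at least 3 slices", call. = FALSE)
  si <- 1 - spec$inner_rate
  sz <- 1 - spec$long_axis_rate
  zc <- mean(range(z))
  new_z <- zc + (z - zc) * sz
  out <- stack
  rings_in <- c("lv_inner", "rv_inner")
  rings_out <- c("lv_outer", "rv_outer")
  for (i in seq_along(out$slices)) {
    sl <- out$slices[[i]]
    sl$z <- new_z[i]
    for (ring in rings_in)
      if (!is.null(sl[[ring]]))
        sl[[ring]] <- scale_about(sl[[ring]], polygon_centroid(sl[[ring]]), si)
    if (!is.null(sl$rv_loops)) {
      ctr <- polygon_centroid(stack$slices[[i]]$rv_inner)
      sl$rv_loops$inner_loop <- scale_about(sl$rv_loops$inner_loop, ctr, si)
    }
    out$slices[[i]] <- sl
  }
  # conservation: sum_j w'_j (s^2 A_out,j - A'_in,j) = V0 (per ring group)
  v0 <- wall_volume(stack) * 1000
  w_new <- simpson_weights(new_z)
  a_out <- cavity_areas(out, "lv_outer") + cavity_areas(out, "rv_outer")
  a_in <- cavity_areas(out, "lv_inner") + cavity_areas(out, "rv_inner")
  apply_outer <- function(i, s) {
    sl <- out$slices[[i]]
    for (ring in rings_out)
      if (!is.null(sl[[ring]]))
        sl[[ring]] <- scale_about(sl[[ring]], polygon_centroid(sl[[ring]]), s)
    if (!is.null(sl$rv_loops)) {
      ctr <- polygon_centroid(stack$slices[[i]]$rv_outer)
      sl$rv_loops$outer_loop <- scale_about(sl$rv_loops$outer_loop, ctr, s)
    }
    sl
  }
  if (spec$scope == "global") {
    s2 <- (v0 + sum(w_new * a_in)) / sum(w_new * a_out)
    if (!is.finite(s2) || s2 <= 0)
      stop("wall-conservation equation has no positive root", call. = FALSE)
    s <- sqrt(s2)
    for (i in seq_along(out$slices)) out$slices[[i]] <- apply_outer(i, s)
    attr(out, "outer_scale") <- s
  } else {
    w_old <- simpson_weights(z)
    s_vec <- numeric(length(z))
    for (i in seq_along(out$slices)) {
      target <- w_old[i] * (a_out_area_old(stack, i))
      s2 <- (target * 1 / w_new[i] + a_in[i]) / a_out[i]
      if (!is.finite(s2) || s2 <= 0)
        stop("wall-conservation equation has no positive root on slice ", i,
             call. = FALSE)
      s_vec[i] <- sqrt(s2)
      out$slices[[i]] <- apply_outer(i, s_vec[i])
    }
    attr(out, "outer_scale") <- s_vec
  }
  out
}

a_out_area_old <- function(stack, i) {
  sl <- stack$slices[[i]]
  a <- 0
  for (pair in list(c("lv_outer", "lv_inner"), c("rv_outer", "rv_inner"))) {
    if (!is.null(sl[[pair[1]]]))
      a <- a + polygon_area(sl[[pair[1]]]) - polygon_area(sl[[pair[2]]])
  }
  a
}

simpson_weights <- function(z) {
  n <- length(z)
  h <- diff(z)[1]
  n_int <- n - 1
  w <- numeric(n)
  n_simpson <- if (n_int %% 2 == 0) n_int else n_int - 1
  if (n_simpson >= 2) {
    ww <- rep(c(2, 4), length.out = n_simpson + 1)
    ww[1] <- 1; ww[n_simpson + 1] <- 1
    w[seq_len(n_simpson + 1)] <- w[seq_len(n_simpson + 1)] + h / 3 * ww
  }
  if (n_int > n_simpson) {
    w[n - 1] <- w[n - 1] + h / 2
    w[n] <- w[n] + h / 2
  }
  w
}

#' Calibrate material stiffness scales to target cavity volumes
#'
#' Adjusts a joint multiplier of (c1, D1, K1) per cardiac phase until the
#' pressurized RV volume of the model matches the in-vivo target volume to
#' within `tolerance` (relative). The end-diastolic anchor is solved under
#' peak pressure with the begin-ejection (end-filling) parameter set; the
#' end-systolic anchor under minimum pressure with the begin-filling
#' (end-ejection) set. Root finding uses the secant method on the log scale
#' with bracketing safeguards.
#'
#' @param volume_fn Function `(scale, anchor)` returning the simulated RV
#'   volume (ml) for `anchor` in `c("ED", "ES")` (see [make_volume_fn()]).
#' @param target_edv,target_esv Target volumes (ml).
#' @param tolerance Relative volume tolerance (default 0.002, i.e. 0.2%).
#' @param max_iter Maximum secant iterations per anchor (default 25).
#' @return Object of class `calibration_state`: `scales` (named ED/ES),
#'   `history` (data frame: anchor, iteration, scale, volume_ml, rel_error),
#'   `tolerance`.
#' @export
calibrate_materials <- function(volume_fn, target_edv, target_esv,
                                tolerance = 0.002, max_iter = 25) {
  vb_stopifnot(target_edv > 0 && target_esv > 0 && target_esv < target_edv,
               "need 0 < target_esv < target_edv")
  hist <- list()
  solve_anchor <- function(anchor, target) {
    ls0 <- 0
    v0 <- volume_fn(exp(ls0), anchor)
    rec <- function(it, ls, v)
      hist[[length(hist) + 1]] <<- data.frame(
        anchor = anchor, iteration = it, scale = exp(ls), volume_ml = v,
        rel_error = (v - target) / target)
    rec(0, ls0, v0)
    if (abs(v0 - target) / target < tolerance) return(exp(ls0))
    # stiffer => smaller volume: pick the second point on the right side
    ls1 <- if (v0 > target) log(1.6) else log(1 / 1.6)
    v1 <- volume_fn(exp(ls1), anchor)
    rec(1, ls1, v1)
    it <- 1
    extra <- 0L
    while (abs(v1 - target) / target >= tolerance ||
           # a few refinement steps beyond the acceptance tolerance pin the
           # stiffness scale itself, not only the volume
           (extra < 3 && abs(v1 - target) / target >= tolerance / 50)) {
      if (abs(v1 - target) / target < tolerance) extra <- extra + 1L
      if (it >= max_iter) {
        err <- structure(class = c("calibration_error", "error", "condition"),
                         list(message = sprintf(
                           "calibration did not converge for %s anchor", anchor),
                           call = NULL,
                           history = do.call(rbind, hist)))
        stop(err)
      }
      denom <- v1 - v0
      if (abs(denom) < 1e-12) denom <- sign(denom + 1e-30) * 1e-12
      ls2 <- ls1 - (v1 - target) * (ls1 - ls0) / denom
      step <- ls2 - ls1
      step <- max(min(step, log(4)), -log(4))  # safeguard large secant jumps
      ls2 <- ls1 + step
      v2 <- volume_fn(exp(ls2), anchor)
      it <- it + 1
      rec(it, ls2, v2)
      ls0 <- ls1; v0 <- v1; ls1 <- ls2; v1 <- v2
    }
    exp(ls1)
  }
  s_ed <- solve_anchor("ED", target_edv)
  s_es <- solve_anchor("ES", target_esv)
  structure(list(scales = c(ED = s_ed, ES = s_es),
                 history = do.call(rbind, hist),
                 tolerance = tolerance),
            class = "calibration_state")
}

#' @export
print.calibration_state <- function(x, ...) {
  cat(sprintf("<calibration_state> scale ED = %.4f, ES = %.4f (tol %.1f%%)\n",
              x$scales["ED"], x$scales["ES"], 100 * x$tolerance))
  invisible(x)
}
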