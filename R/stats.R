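#' Right-ventricular ejection fraction
#'
#' EF = (EDV - ESV) / EDV x 100, the single outcome measure used to grade
#' band-insertion surgery plans.
#'
#' @param edv End-diastolic volume (ml), must be positive.
#' @param esv End-systolic volume (ml), in `[0, edv]`.
#' @return Ejection fraction in percent. Vectorized over `edv`/`esv`.
#' @examples
#' ejection_fraction(406.91, 254.49)  # 37.46
#' @export
ejection_fraction <- function(edv, esv) {
  vb_stopifnot(all(edv > 0), "edv must be positive")
  vb_stopifnot(all(esv >= 0), "esv must be non-negative")
  if (any(esv > edv)) stop("esv exceeds edv", call. = FALSE)
  (edv - esv) / edv * 100
}

#' Ejection-fraction improvement
#'
#' Difference between post-operative and pre-operative (baseline) EF, in
#' absolute percentage points; sign is preserved.
#'
#' @param post_ef,pre_ef EF values in percent.
#' @return `post_ef - pre_ef`.
#' @export
delta_ef <- function(post_ef, pre_ef) post_ef - pre_ef

#' Cavity volume of a single-cavity contour stack by Simpson's method
#'
#' Composite Simpson combination of planar slice areas times slice spacing;
#' for an even number of intervals the final interval is handled by the
#' trapezoid rule.
#'
#' @param areas Planar cross-section areas (mm^2) at each slice, ordered by z.
#' @param z Strictly increasing slice positions (mm), equally spaced.
#' @return Volume in ml (1 ml = 1000 mm^3).
#' @export
simpson_volume <- function(areas, z) {
  n <- length(z)
  if (n < 3) stop("need at least 3 slices", call. = FALSE)
  vb_stopifnot(length(areas) == n, "areas and z lengths differ")
  dz <- diff(z)
  if (any(dz <= 0)) stop("z positions must be strictly increasing", call. = FALSE)
  vb_stopifnot(max(abs(dz - dz[1])) < 1e-6 * dz[1] + 1e-12,
               "slices must be equally spaced")
  h <- dz[1]
  n_int <- n - 1
  vol <- 0
  n_simpson <- if (n_int %% 2 == 0) n_int else n_int - 1
  if (n_simpson >= 2) {
    idx <- seq(1, n_simpson + 1)
    w <- rep(c(2, 4), length.out = n_simpson + 1)
    w[1] <- 1
    w[n_simpson + 1] <- 1
    vol <- vol + h / 3 * sum(w * areas[idx])
  }
  if (n_int > n_simpson) {
    vol <- vol + h / 2 * (areas[n - 1] + areas[n])
  }
  vol / 1000
}

#' Largest eigenvalue of a symmetric 3x3 tensor
#'
#' Maximum principal value, used to reduce stress and strain tensors to the
#' reported pointwise scalar.
#'
#' @param tensor Symmetric 3x3 matrix.
#' @param tol Asymmetry tolerance relative to the largest entry.
#' @return Largest eigenvalue.
#' @export
max_principal <- function(tensor, tol = 1e-8) {
  vb_stopifnot(is.matrix(tensor) && all(dim(tensor) == c(3, 3)),
               "tensor must be 3x3")
  scale <- max(abs(tensor), 1e-300)
  if (max(abs(tensor - t(tensor))) > tol * scale)
    stop("tensor is not symmetric", call. = FALSE)
  max(eigen(0.5 * (tensor + t(tensor)), symmetric = TRUE,
            only.values = TRUE)$values)
}

#' Mean and sample standard deviation
#'
#' Cohort summary convention: arithmetic mean and SD with the n-1
#' denominator (sample SD).
#'
#' @param values Numeric vector, length >= 1 (>= 2 for a finite SD).
#' @return Named vector `c(mean, sd)`.
#' @export
summarize_mean_sd <- function(values) {
  if (length(values) == 0) stop("empty value list", call. = FALSE)
  c(mean = mean(values), sd = if (length(values) >= 2) sd(values) else NA_real_)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided exact p-value from the full sign-assignment null distribution of
#' the signed-rank statistic. Zero differences are dropped before ranking
#' (Pratt/zero-exclusion as in classical exact tables); tied absolute
#' differences receive average ranks, in which case the null distribution is
#' enumerated over all 2^n sign assignments. Without ties a dynamic program
#' over integer ranks gives the same distribution.
#'
#' @param a,b Paired measurement vectors of equal length (n <= 25 after
#'   removing zero differences).
#' @return List with `statistic` (V, sum of positive ranks), `n` (pairs used)
#'   and `p.value` (two-sided exact).
#' @export
wilcoxon_signed_rank_exact <- function(a, b) {
  vb_stopifnot(length(a) == length(b), "paired vectors differ in length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, n = 0L, p.value = 1))
  }
  if (n > 25) stop("exact enumeration limited to n <= 25", call. = FALSE)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (!ties) {
    # distribution of V over 2^n assignments via convolution on integer ranks
    maxv <- n * (n + 1) / 2
    cnt <- numeric(maxv + 1)
    cnt[1] <- 1
    for (k in seq_len(n)) {
      shifted <- c(rep(0, k), cnt)[seq_len(maxv + 1)]
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    support <- 0:maxv
  } else {
    if (n > 20) stop("tied ranks: enumeration limited to n <= 20", call. = FALSE)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% r)
    tab <- table(vs)
    support <- as.numeric(names(tab))
    probs <- as.vector(tab) / 2^n
  }
  p_le <- sum(probs[support <= v + 1e-9])
  p_ge <- sum(probs[support >= v - 1e-9])
  p <- min(1, 2 * min(p_le, p_ge))
  list(statistic = v, n = as.integer(n), p.value = p)
}

#' Printed cohort and results tables bundled with the package
#'
#' Loads the per-patient demographic/volume table, the 20%-contraction
#' results per plan, the plan-E results per contraction ratio, or the
#' cohort-summary table, as data frames.
#'
#' @param which One of `"cohort"`, `"plans20"`, `"planE"`, `"summary"`.
#' @return A data frame.
#' @export
load_reference_table <- function(which = c("cohort", "plans20", "planE", "summary")) {
  which <- match.arg(which)
  file <- switch(which,
    cohort  = "reference_cohort.csv",
    plans20 = "reference_results_plans20.csv",
    planE   = "reference_results_planE.csv",
    summary = "reference_summary.csv")
  read.csv(vb_extdata(file), stringsAsFactors = FALSE)
}

#' Baseline (no-band) per-patient EF reconstructed from the results tables
#'
#' The per-plan tables report post-operative EF and the improvement over the
#' same patient's baseline, so baseline EF = EF - dEF for any plan row; the
#' plan-A and plan-E rows agree to printed precision.
#'
#' @return Named numeric vector of baseline EF (percent) per patient.
#' @export
baseline_ef_from_tables <- function() {
  t4 <- load_reference_table("plans20")
  e <- t4[t4$plan == "E", ]
  setNames(e$ef_pct - e$delta_ef_pct, e$patient)
}

#' Sample stress/strain scalars along RV endocardial slice curves
#'
#' Places `n_per_slice` points evenly spaced by arc length along each slice's
#' deformed right-ventricular endocardial ring and returns the maximum
#' principal value of the element tensor underlying each point.
#'
#' @param mesh A `ventricle_mesh`.
#' @param disp N x 3 nodal displacement matrix (mm).
#' @param elem_tensors M x 6 matrix of per-element symmetric tensors in Voigt
#'   order (11, 22, 33, 12, 23, 13).
#' @param n_per_slice Points per slice (default 100).
#' @return Data frame with columns `slice`, `arc`, `value` (max principal).
#' @export
sample_surface_stress <- function(mesh, disp, elem_tensors, n_per_slice = 100) {
  rings <- rv_endocardial_rings(mesh)
  if (length(rings) == 0) stop("mesh has no RV endocardial rings", call. = FALSE)
  out <- vector("list", length(rings))
  x <- mesh$nodes + disp
  for (s in seq_along(rings)) {
    ring <- rings[[s]]
    nodes <- ring$nodes
    pts <- x[nodes, , drop = FALSE]
    closed <- rbind(pts, pts[1, ])
    seg <- sqrt(rowSums(diff(closed)^2))
    cum <- c(0, cumsum(seg))
    total <- cum[length(cum)]
    tgt <- seq(0, total, length.out = n_per_slice + 1)[seq_len(n_per_slice)]
    seg_id <- findInterval(tgt, cum, rightmost.closed = TRUE)
    seg_id[seg_id > length(nodes)] <- length(nodes)
    vals <- vapply(seq_len(n_per_slice), function(i) {
      e <- ring$elements[seg_id[i]]
      max_principal(voigt_to_matrix(elem_tensors[e, ]))
    }, numeric(1))
    out[[s]] <- data.frame(slice = s, arc = tgt, value = vals)
  }
  do.call(rbind, out)
}

voigt_to_matrix <- function(v) {
  matrix(c(v[1], v[4], v[6],
           v[4], v[2], v[5],
           v[6], v[5], v[3]), 3, 3)
}

matrix_to_voigt <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[2, 3], m[1, 3])
}
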