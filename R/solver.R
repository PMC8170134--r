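# Quasi-static equilibrium of the bi-ventricle + band assembly.
#
# Newton iteration on the total-Lagrangian residual with follower cavity
# pressures; load increments are bisected on divergence. The basal ring is
# fixed longitudinally with in-plane freedom; per body, two in-plane anchor
# components suppress the remaining rigid modes.

#' Assemble the solvable system for a mesh
#'
#' Precomputes cavity face lists, Dirichlet constraints and the sparse
#' stiffness pattern. Band endpoints (if any) must be fixed here because
#' they enter the sparsity pattern.
#'
#' @param mesh A `ventricle_mesh` with fibers assigned.
#' @param band_nodes Integer matrix (n_bands x 2) of band endpoint node ids.
#' @param fix_all_z Constrain every z displacement (plane-strain harness for
#'   verification problems).
#' @param freeze_body Optional body name (`"LV"`) whose nodes are held
#'   fixed. The two wall bodies are mechanically uncoupled, so a battery
#'   can solve the LV once with the baseline and restrict band models to
#'   the RV.
#' @return Object of class `fe_system`.
#' @export
fe_system <- function(mesh, band_nodes = matrix(integer(0), 0, 2),
                      fix_all_z = FALSE, freeze_body = NULL) {
  N <- nrow(mesh$nodes)
  faces <- NULL; face_cavity <- character(0)
  for (cav in names(mesh$cavity_faces)) {
    f <- mesh$cavity_faces[[cav]]
    faces <- rbind(faces, f)
    face_cavity <- c(face_cavity, rep(cav, nrow(f)))
  }
  fixed <- matrix(FALSE, N, 3)
  for (body in names(mesh$grids)) {
    g <- mesh$grids[[body]]
    basal <- unique(as.vector(g[mesh$n_slices, , ]))
    fixed[basal, 3] <- TRUE
    if (fix_all_z) {
      # plane-strain harness: constrain z everywhere, pin two in-plane
      # anchor components per body against rigid modes
      fixed[, 3] <- TRUE
      ring <- unique(g[mesh$n_slices, , 1])
      n1 <- ring[1]
      n2 <- ring[max(2, floor(length(ring) / 2))]
      fixed[n1, 1:2] <- TRUE
      d <- mesh$nodes[n2, 1:2] - mesh$nodes[n1, 1:2]
      perp <- c(-d[2], d[1])
      fixed[n2, which.max(abs(perp))] <- TRUE
    } else {
      # closed-apex idealization: clamp the apical ring (the truncated apex
      # stands in for the real closed apex), base fixed longitudinally only
      apical <- unique(as.vector(g[1, , ]))
      fixed[apical, ] <- TRUE
    }
  }
  if (!is.null(freeze_body)) {
    vb_stopifnot(freeze_body %in% names(mesh$grids), "unknown body to freeze")
    fixed[unique(as.vector(mesh$grids[[freeze_body]])), ] <- TRUE
    keep <- face_cavity != freeze_body
    faces <- faces[keep, , drop = FALSE]
    face_cavity <- face_cavity[keep]
  }
  fixed_v <- as.vector(t(fixed))            # dof order: node-major (x,y,z)
  dofmap <- integer(3 * N)
  dofmap[!fixed_v] <- seq_len(sum(!fixed_v))
  storage.mode(band_nodes) <- "integer"
  pat <- fe_pattern(mesh$elems, faces, cbind(band_nodes,
                                             matrix(0, nrow(band_nodes), 4)),
                    dofmap)
  nf <- sum(!fixed_v)
  live <- pat$i > 0
  key <- (pat$j - 1) * as.double(nf) + pat$i
  ukey <- unique(key[live])
  ord <- order((ukey - 1) %/% nf, (ukey - 1) %% nf)  # column-major like dgC
  ukey <- ukey[ord]
  ui <- as.integer((ukey - 1) %% nf) + 1L
  uj <- as.integer((ukey - 1) %/% nf) + 1L
  skeleton <- Matrix::sparseMatrix(i = ui, j = uj, x = 0, dims = c(nf, nf))
  pos <- match(key, ukey)
  pos[!live] <- 0L
  xmap <- as.integer(pos)
  # symmetrization machinery: the tangent is mildly nonsymmetric (follower
  # pressure); Newton uses the symmetrized tangent with a cached CHOLMOD
  # symbolic factorization, falling back to sparse LU when indefinite
  tmp <- skeleton
  tmp@x <- as.double(seq_along(tmp@x))
  tperm <- as.integer(Matrix::t(tmp)@x)
  ssym <- Matrix::forceSymmetric(tmp, uplo = "U")
  sym_map <- as.integer(ssym@x)
  ssym@x <- numeric(length(sym_map))
  structure(list(mesh = mesh, faces = faces, face_cavity = face_cavity,
                 fixed = fixed_v, dofmap = dofmap, nf = nf,
                 skeleton = skeleton, xmap = xmap, nnz = length(ukey),
                 band_nodes = band_nodes,
                 tperm = tperm, sym_map = sym_map, sym_skeleton = ssym,
                 cache = new.env(parent = emptyenv())),
            class = "fe_system")
}

empty_bands <- function() matrix(numeric(0), 0, 6)

`%||%` <- function(a, b) if (is.null(a)) b else a

newton_solve <- function(sys, u, matpar, face_p, bands,
                         tol = 1e-6, max_iter = 24) {
  mesh <- sys$mesh
  free <- !sys$fixed
  A <- sys$skeleton
  res_prev <- Inf
  bad_steps <- 0
  rn_hist <- numeric(max_iter)
  for (it in seq_len(max_iter)) {
    asm <- fe_assemble(mesh$nodes, mesh$elems, u, matpar, mesh$fiber,
                       sys$faces, face_p, bands, sys$dofmap, sys$xmap,
                       sys$nnz, TRUE)
    if (!asm$ok) return(list(u = u, converged = FALSE, reason = "invalid_state"))
    r <- (asm$fint - asm$fext)[free]
    ref <- max(sqrt(sum(asm$fext[free]^2)), sqrt(sum(asm$fint[free]^2)), 1e-6)
    rn <- sqrt(sum(r^2))
    if (!is.finite(rn))
      return(list(u = u, converged = FALSE, reason = "invalid_state"))
    # absolute floor (mN): guards the unloaded state against roundoff
    if (rn <= max(tol * ref, 1e-9))
      return(list(u = u, converged = TRUE, iters = it, res = rn / ref,
                  fext = asm$fext, fint = asm$fint))
    rn_hist[it] <- rn
    # stagnation: no new best residual for six iterations -> let the
    # continuation bisect instead of burning the iteration budget
    if (it - which.min(rn_hist[seq_len(it)]) >= 6)
      return(list(u = u, converged = FALSE, reason = "stagnation"))
    xs <- 0.5 * (asm$x + asm$x[sys$tperm])
    S <- sys$sym_skeleton
    S@x <- xs[sys$sym_map]
    du <- tryCatch({
      ch <- if (is.null(sys$cache$chol))
        Matrix::Cholesky(S, LDL = TRUE) else Matrix::update(sys$cache$chol, S)
      sys$cache$chol <- ch
      as.numeric(Matrix::solve(ch, -r, system = "A"))
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(du) || !all(is.finite(du))) {
      A@x <- asm$x
      A@factors <- list()   # invalidate any cached factorization
      du <- tryCatch(as.numeric(Matrix::solve(A, -r)),
                     error = function(e) NULL)
    }
    if (is.null(du) || !all(is.finite(du)))
      return(list(u = u, converged = FALSE, reason = "singular"))
    # nonmonotone backtracking: a transient residual rise is tolerated for a
    # few iterations (typical with follower pressure near the start)
    alpha <- 1
    accepted <- FALSE
    full_step <- NULL
    for (ls in 1:5) {
      u_try_v <- as.vector(t(u))
      u_try_v[free] <- u_try_v[free] + alpha * du
      u_try <- matrix(u_try_v, ncol = 3, byrow = TRUE)
      a2 <- fe_assemble(mesh$nodes, mesh$elems, u_try, matpar, mesh$fiber,
                        sys$faces, face_p, bands, sys$dofmap, sys$xmap,
                        sys$nnz, FALSE)
      if (a2$ok) {
        rn2 <- sqrt(sum(((a2$fint - a2$fext)[free])^2))
        if (!is.finite(rn2)) rn2 <- Inf
        if (ls == 1 && is.finite(rn2)) full_step <- list(u = u_try, rn = rn2)
        if (rn2 < rn || rn2 <= max(tol * ref, 1e-9)) {
          u <- u_try; accepted <- TRUE; break
        }
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      if (!is.null(full_step) && full_step$rn < 10 * rn && bad_steps < 3) {
        u <- full_step$u
        bad_steps <- bad_steps + 1
      } else {
        return(list(u = u, converged = FALSE, reason = "linesearch"))
      }
    } else if (alpha == 1) bad_steps <- 0
    res_prev <- rn
  }
  list(u = u, converged = FALSE, reason = "max_iter")
}

# march from one equilibrium state to a target state, bisecting on failure;
# u_guess (optional) is a predictor for the full-step Newton start and
# step0 the initial increment fraction (carried across calls as a hint)
static_march <- function(sys, u0, state_from, state_to,
                         tol = 1e-6, max_bisect = 10, u_guess = NULL,
                         step0 = 1) {
  interp <- function(s) {
    list(matpar = (1 - s) * state_from$matpar + s * state_to$matpar,
         face_p = (1 - s) * state_from$face_p + s * state_to$face_p,
         bands = if (nrow(state_to$bands) == 0) state_to$bands else {
           b <- state_to$bands
           b[, 3] <- (1 - s) * state_from$bands[, 3] + s * state_to$bands[, 3]
           b[, 4] <- (1 - s) * state_from$bands[, 4] + s * state_to$bands[, 4]
           b
         })
  }
  u <- u0
  s_done <- 0; step <- max(min(step0, 1), 2^-8)
  step_min_used <- 1
  n_fail <- 0
  attempts <- 0
  while (s_done < 1 - 1e-12) {
    attempts <- attempts + 1
    if (attempts > 120)
      stop("equilibrium continuation stalled (120 increments without ",
           "reaching the load target)", call. = FALSE)
    s_try <- min(1, s_done + step)
    st <- interp(s_try)
    u_start <- if (attempts == 1 && s_try == 1 && !is.null(u_guess))
      u_guess else u
    sol <- newton_solve(sys, u_start, st$matpar, st$face_p, st$bands,
                        tol = tol)
    if (sol$converged) {
      u <- sol$u
      s_done <- s_try
      last <- sol
      step_min_used <- min(step_min_used, step)
      step <- min(step * 2, 1 - s_done + 1e-15)
      n_fail <- 0
    } else {
      n_fail <- n_fail + 1
      step <- step / 2
      if (n_fail > max_bisect)
        stop("equilibrium iteration diverged (", sol$reason,
             ") at load fraction ", signif(s_done, 3), call. = FALSE)
    }
  }
  last$u_mat <- u
  last$step_min <- step_min_used
  last
}

#' Solve quasi-static equilibrium at prescribed pressures
#'
#' Ramps cavity pressures (and band state) from zero load to the target and
#' returns the converged displacement field. The outer surface is
#' traction-free; basal ring longitudinally fixed.
#'
#' @param sys An [fe_system()].
#' @param matpar M x 7 per-element material matrix
#'   (c1, c2, D1, D2, K1, K2, kappa), e.g. from [material_matrix()].
#' @param p_rv,p_lv Cavity pressures (kPa).
#' @param bands Band state matrix (n x 6: node_a, node_b, L0, c1, area,
#'   tension_only) or `NULL`.
#' @param u0 Optional initial displacement (N x 3).
#' @param tol Relative residual tolerance (default 1e-6).
#' @return List: `u` (N x 3 displacement, mm), `residual` (relative), and
#'   nodal force vectors.
#' @export
solve_equilibrium <- function(sys, matpar, p_rv, p_lv, bands = NULL,
                              u0 = NULL, tol = 1e-6) {
  vb_stopifnot(p_rv >= 0 && p_lv >= 0, "pressures must be non-negative")
  mesh <- sys$mesh
  if (is.null(bands)) bands <- empty_bands()
  if (is.null(u0)) u0 <- matrix(0, nrow(mesh$nodes), 3)
  face_p <- ifelse(sys$face_cavity == "RV", p_rv, p_lv)
  zero_bands <- bands
  state_to <- list(matpar = matpar, face_p = face_p, bands = bands)
  state_from <- list(matpar = matpar, face_p = 0 * face_p, bands = zero_bands)
  sol <- static_march(sys, u0, state_from, state_to, tol = tol)
  list(u = sol$u_mat, residual = sol$res, fint = sol$fint, fext = sol$fext,
       iters = sol$iters)
}

#' Cavity volume of the (deformed) mesh by the divergence theorem
#'
#' The cavity surface is the endocardial quad sheet closed by planar caps at
#' the apical and basal slice rings; the surface is checked for closure
#' (every edge shared by exactly two facets).
#'
#' @param mesh A `ventricle_mesh`.
#' @param cavity `"RV"` or `"LV"`.
#' @param disp Optional N x 3 displacement.
#' @return Volume in ml.
#' @export
cavity_volume <- function(mesh, cavity = c("RV", "LV"), disp = NULL) {
  cavity <- match.arg(cavity)
  if (!cavity %in% names(mesh$cavity_faces))
    stop("mesh has no ", cavity, " cavity", call. = FALSE)
  x <- mesh$nodes
  if (!is.null(disp)) x <- x + disp
  quads <- mesh$cavity_faces[[cavity]]
  g <- mesh$grids[[cavity]]
  ring_ids <- function(s) {
    ids <- g[s, , 1]
    ids[!duplicated(ids)]
  }
  tris <- list()
  add_tri <- function(a, b, cc) tris[[length(tris) + 1]] <<- c(a, b, cc)
  for (q in seq_len(nrow(quads))) {
    add_tri(quads[q, 1], quads[q, 2], quads[q, 3])
    add_tri(quads[q, 1], quads[q, 3], quads[q, 4])
  }
  for (side in c("bottom", "top")) {
    s <- if (side == "bottom") 1L else mesh$n_slices
    ring <- ring_ids(s)
    ctr_id <- -s  # virtual centroid node
    K <- length(ring)
    for (k in seq_len(K)) {
      k2 <- if (k == K) 1L else k + 1L
      if (side == "top") add_tri(ctr_id, ring[k], ring[k2])
      else add_tri(ctr_id, ring[k2], ring[k])
    }
  }
  # closure check on real edges
  edges <- character(0)
  for (t in tris) {
    for (pair in list(t[1:2], t[2:3], t[c(3, 1)])) {
      if (any(pair < 0)) next
      edges <- c(edges, paste(sort(pair), collapse = "-"))
    }
  }
  et <- table(edges)
  # cap-rim edges appear once from the sheet plus caps close them virtually
  rim <- c(ring_ids(1L), ring_ids(mesh$n_slices))
  bad <- names(et)[et != 2]
  bad_nodes <- unique(as.integer(unlist(strsplit(bad, "-"))))
  if (length(setdiff(bad_nodes, rim)) > 0)
    stop("cavity surface is not closed", call. = FALSE)
  ctr_bot <- colMeans(x[ring_ids(1L), , drop = FALSE])
  ctr_top <- colMeans(x[ring_ids(mesh$n_slices), , drop = FALSE])
  getp <- function(id) {
    if (id > 0) return(x[id, ])
    if (id == -1L) return(ctr_bot)
    ctr_top
  }
  v <- 0
  for (t in tris) {
    p1 <- getp(t[1]); p2 <- getp(t[2]); p3 <- getp(t[3])
    v <- v + (p1[1] * (p2[2] * p3[3] - p2[3] * p3[2]) -
              p1[2] * (p2[1] * p3[3] - p2[3] * p3[1]) +
              p1[3] * (p2[1] * p3[2] - p2[2] * p3[1])) / 6
  }
  if (v <= 0) stop("non-positive cavity volume (orientation?)", call. = FALSE)
  v / 1000
}

#' Relative L2 periodicity metric between two simulated cycles
#'
#' Space-time L2 norm of the field difference over the RV wall and one
#' cycle, normalized by the norm of the current cycle, evaluated for the
#' maximum-principal stress and strain fields; the larger of the two is
#' returned.
#'
#' @param prev,curr Lists with `stress_p1` and `strain_p1` (elements x time
#'   matrices on matched grids).
#' @param w_elem Element volume weights (restrict to the RV domain upstream).
#' @return Relative difference (dimensionless).
#' @export
cycle_convergence <- function(prev, curr, w_elem) {
  one <- function(a, b) {
    if (!all(dim(a) == dim(b))) stop("mismatched cycle grids", call. = FALSE)
    num <- sqrt(sum(w_elem * rowSums((a - b)^2)))
    den <- sqrt(sum(w_elem * rowSums(b^2)))
    if (den == 0) return(0)
    num / den
  }
  max(one(prev$stress_p1, curr$stress_p1),
      one(prev$strain_p1, curr$strain_p1))
}

#' Per-element material matrix at a cycle phase
#'
#' Blends the phase-anchored parameter sets (begin-ejection anchor =
#' end-filling rows, begin-filling anchor = end-ejection rows) with the
#' cosine phase weight and applies the calibrated per-phase stiffness
#' scales to the myocardial (c1, D1, K1). Scar and patch are
#' phase-independent. The volumetric penalty is `kappa_factor` times the
#' largest c1 present.
#'
#' @param mesh A `ventricle_mesh`.
#' @param mats Material catalogue from [default_materials()].
#' @param w Phase blend weight in `[0, 1]` (0 = begin ejection).
#' @param scales Named vector `c(ED=, ES=)` of stiffness multipliers.
#' @param kappa_factor Penalty multiplier (default 1000).
#' @return M x 7 matrix (c1, c2, D1, D2, K1, K2, kappa).
#' @export
material_matrix <- function(mesh, mats, w, scales = c(ED = 1, ES = 1),
                            kappa_factor = 1000) {
  M <- nrow(mesh$elems)
  out <- matrix(0, M, 7)
  get6 <- function(p, scale = 1)
    c(p$c1 * scale, p$c2, p$D1 * scale, p$D2, p$K1 * scale, p$K2)
  row_for <- function(region, layer) {
    if (region %in% c("LV", "RV", "septum")) {
      key_ed <- paste0("myo_", layer, ".end_filling")
      key_es <- paste0("myo_", layer, ".end_ejection")
      (1 - w) * get6(mats[[key_ed]], scales["ED"]) +
        w * get6(mats[[key_es]], scales["ES"])
    } else if (region == "scar") {
      get6(mats[["scar.all"]])
    } else if (region == "patch") {
      get6(mats[["patch.all"]])
    } else stop("unknown region ", region, call. = FALSE)
  }
  keys <- paste(mesh$region, mesh$layer)
  for (k in unique(keys)) {
    parts <- strsplit(k, " ")[[1]]
    out[keys == k, 1:6] <- matrix(row_for(parts[1], parts[2]), nrow = sum(keys == k),
                                  ncol = 6, byrow = TRUE)
  }
  out[, 7] <- kappa_factor * max(out[, 1])
  out
}

#' Simulate the cardiac cycle to periodic convergence
#'
#' Marches the quasi-static model through the pressure schedule, repeating
#' cycles until the periodicity metric (relative space-time L2 difference of
#' the maximum-principal stress and strain fields over the RV wall) falls
#' below `conv_tol`. Because the model is quasi-static the metric typically
#' converges at the second cycle.
#'
#' @param model A model from [vb_model()].
#' @param max_cycles Maximum cycles (default 10).
#' @param conv_tol Periodicity tolerance (default 1e-3, i.e. 0.1%).
#' @return Object of class `simulation_result`: per-time volumes and cavity
#'   pressures, EDV/ESV/EF, surface-sampled stress/strain summaries at the
#'   begin-filling and begin-ejection anchors, convergence history.
#' @export
simulate_cycle <- function(model, max_cycles = 10, conv_tol = 1e-3) {
  sys <- model$sys
  mesh <- sys$mesh
  sch <- model$pressures
  nt <- length(sch$times)
  states <- lapply(seq_len(nt), function(i) {
    w <- phase_weight(sch$times[i], sch$systole_fraction)
    list(matpar = material_matrix(mesh, model$materials, w, model$scales,
                                  model$kappa_factor),
         face_p = ifelse(sys$face_cavity == "RV", sch$p_rv[i], sch$p_lv[i]),
         bands = model$band_state_fn(sys, w))
  })
  u <- matrix(0, nrow(mesh$nodes), 3)
  u_prev <- NULL
  rv_elems <- mesh$body == "RV"
  ref_fields <- fe_fields(mesh$nodes, mesh$elems, u, states[[1]]$matpar,
                          mesh$fiber)
  w_elem <- ref_fields$ref_volume[rv_elems]
  conv_hist <- numeric(0)
  prev_cycle <- NULL
  result <- NULL
  for (cyc in seq_len(max_cycles)) {
    sp1 <- matrix(0, sum(rv_elems), nt)
    ep1 <- matrix(0, sum(rv_elems), nt)
    vols <- matrix(0, nt, 2)
    anchors <- list()
    for (i in seq_len(nt)) {
      if (i == 1 && cyc == 1) {
        sol <- NULL
        if (!is.null(model$u0)) {
          # warm start from the calibrated end-diastolic state
          try0 <- newton_solve(sys, model$u0, states[[1]]$matpar,
                               states[[1]]$face_p, states[[1]]$bands)
          if (try0$converged) { try0$u_mat <- try0$u; sol <- try0 }
        }
        if (is.null(sol)) {
          from_state <- list(matpar = states[[1]]$matpar,
                             face_p = 0 * states[[1]]$face_p,
                             bands = states[[1]]$bands)
          sol <- static_march(sys, u, from_state, states[[1]])
        }
      } else {
        from_state <- if (i == 1) states[[nt]] else states[[i - 1]]
        guess <- if (!is.null(u_prev)) u + (u - u_prev) else NULL
        sol <- static_march(sys, u, from_state, states[[i]],
                            u_guess = guess)
      }
      u_prev <- u
      u <- sol$u_mat
      fl <- fe_fields(mesh$nodes, mesh$elems, u, states[[i]]$matpar, mesh$fiber)
      sp1[, i] <- fl$stress_p1[rv_elems]
      ep1[, i] <- fl$strain_p1[rv_elems]
      vols[i, 1] <- cavity_volume(mesh, "RV", u)
      vols[i, 2] <- if ("LV" %in% names(mesh$cavity_faces))
        cavity_volume(mesh, "LV", u) else NA_real_
      if (i %in% c(sch$begin_ejection, sch$begin_filling))
        anchors[[as.character(i)]] <- list(u = u, fields = fl)
    }
    curr_cycle <- list(stress_p1 = sp1, strain_p1 = ep1)
    if (!is.null(prev_cycle)) {
      m <- cycle_convergence(prev_cycle, curr_cycle, w_elem)
      conv_hist <- c(conv_hist, m)
      if (m < conv_tol) {
        result <- list(vols = vols, cycle_fields = curr_cycle,
                       anchors = anchors, cycles = cyc)
        break
      }
    }
    prev_cycle <- curr_cycle
  }
  if (is.null(result))
    stop(paste0("cycle iteration did not reach periodic convergence; ",
                "metrics: ", paste(signif(conv_hist, 3), collapse = ", ")),
         call. = FALSE)
  ibe <- sch$begin_ejection; ibf <- sch$begin_filling
  edv <- result$vols[ibe, 1]; esv <- result$vols[ibf, 1]
  surf <- function(i, what) {
    fl <- result$anchors[[as.character(i)]]$fields
    sm <- sample_surface_stress(mesh, result$anchors[[as.character(i)]]$u,
                                fl[[what]], n_per_slice = 100)
    mean(sm$value)
  }
  structure(list(
    volumes = data.frame(time = sch$times, p_rv = sch$p_rv, p_lv = sch$p_lv,
                         rv_volume_ml = result$vols[, 1],
                         lv_volume_ml = result$vols[, 2]),
    edv = edv, esv = esv, ef = ejection_fraction(edv, esv),
    stress_be = surf(ibe, "stress"), strain_be = surf(ibe, "strain"),
    stress_bf = surf(ibf, "stress"), strain_bf = surf(ibf, "strain"),
    convergence = conv_hist, cycles = result$cycles,
    anchors = result$anchors, cycle_fields = result$cycle_fields,
    begin_ejection = ibe, begin_filling = ibf
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(paste0("<simulation_result> EDV %.1f ml, ESV %.1f ml, ",
                     "EF %.2f%%, %d cycle(s), periodicity %.2e\n"),
              x$edv, x$esv, x$ef, x$cycles, min(x$convergence)))
  invisible(x)
}
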