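# Volumetric two-layer hexahedral meshing of stacked wall contours.
#
# Both ventricle walls are rings between nested closed curves on each slice;
# nodes live on a structured (slice, ring-parameter, through-wall level)
# grid. The RV crescent ring collapses to wedge columns at the two horns
# where the cavity thickness vanishes; the collapsed nodes are merged so the
# cavity surface stays watertight.

#' Build a volumetric two-layer mesh from a contour stack
#'
#' @param stack A `contour_stack` (LV contours, and for the RV the matched
#'   boundary loops produced by [generate_contour_stack()]).
#' @param n_theta_mesh Circumferential element count per ring (default 24).
#' @param n_layers Through-wall element layers (default 2, one inner and one
#'   outer, following the two-layer construction used for fiber assignment).
#' @return Object of class `ventricle_mesh`.
#' @export
build_mesh <- function(stack, n_theta_mesh = 24, n_layers = 2) {
  validate_contour_stack(stack)
  n_s <- length(stack$slices)
  z <- stack_z(stack)
  has_lv <- !is.null(stack$slices[[1]]$lv_inner)
  has_rv <- !is.null(stack$slices[[1]]$rv_inner)
  nodes <- matrix(0, 0, 3)
  node_key <- new.env(hash = TRUE)
  add_node <- function(x, y, zz) {
    key <- paste(sprintf("%.9f", x), sprintf("%.9f", y), sprintf("%.9f", zz))
    id <- node_key[[key]]
    if (!is.null(id)) return(id)
    nodes <<- rbind(nodes, c(x, y, zz))
    id <- nrow(nodes)
    node_key[[key]] <- id
    id
  }
  grids <- list()
  loops_meta <- list()

  ring_loops <- function(sl, body) {
    # matched inner/outer boundary loops for one slice of one body
    if (body == "LV") {
      pin <- sl$lv_inner; pout <- sl$lv_outer
      if (nrow(pin) != nrow(pout))
        stop("LV contours must have matching point counts", call. = FALSE)
      list(inner = pin, outer = pout, septal_from = NA_integer_)
    } else {
      if (is.null(sl$rv_loops))
        stop(paste("RV meshing needs the matched boundary loops produced by",
                   "generate_contour_stack (or JSON round-trip)"),
             call. = FALSE)
      list(inner = sl$rv_loops$inner_loop, outer = sl$rv_loops$outer_loop,
           septal_from = sl$rv_loops$n_half + 1L)
    }
  }

  subsample_idx <- function(n, m, body, n_half) {
    if (body == "LV") {
      unique(round(seq(1, n + 1, length.out = m + 1)))[seq_len(m)]
    } else {
      m_half <- max(4L, as.integer(round(m / 2)) + 1L)
      ih <- unique(round(seq(1, n_half, length.out = m_half)))
      c(ih, n_half + (n_half + 1L - rev(ih)))
    }
  }

  for (body in c(if (has_lv) "LV", if (has_rv) "RV")) {
    l0 <- ring_loops(stack$slices[[1]], body)
    n_half <- if (body == "RV") stack$slices[[1]]$rv_loops$n_half else NA
    idx <- subsample_idx(nrow(l0$inner), n_theta_mesh, body, n_half)
    K <- length(idx)
    grid <- array(NA_integer_, c(n_s, K, n_layers + 1))
    for (s in seq_len(n_s)) {
      lo <- ring_loops(stack$slices[[s]], body)
      pin <- lo$inner[idx, , drop = FALSE]
      pout <- lo$outer[idx, , drop = FALSE]
      for (k in seq_len(K)) {
        for (l in 0:n_layers) {
          lam <- l / n_layers
          p <- (1 - lam) * pin[k, ] + lam * pout[k, ]
          grid[s, k, l + 1] <- add_node(p[1], p[2], z[s])
        }
      }
    }
    grids[[body]] <- grid
    fw_k <- if (body == "RV") which(idx <= n_half) else seq_len(K)
    loops_meta[[body]] <- list(K = K, idx = idx, n_half = n_half,
                               freewall_k = fw_k,
                               septal_k = if (body == "RV")
                                 which(idx > n_half) else integer(0))
  }

  elems <- list(); e_body <- c(); e_layer <- c(); e_region <- c()
  e_tab <- list()
  for (body in names(grids)) {
    g <- grids[[body]]
    K <- loops_meta[[body]]$K
    sept_k <- loops_meta[[body]]$septal_k
    for (s in seq_len(n_s - 1)) {
      for (k in seq_len(K)) {
        k2 <- if (k == K) 1L else k + 1L
        for (l in seq_len(n_layers)) {
          c1 <- g[s, k, l];  c2 <- g[s, k, l + 1]
          c3 <- g[s, k2, l + 1]; c4 <- g[s, k2, l]
          c5 <- g[s + 1, k, l]; c6 <- g[s + 1, k, l + 1]
          c7 <- g[s + 1, k2, l + 1]; c8 <- g[s + 1, k2, l]
          if (length(unique(c(c1, c2, c3, c4))) < 3) next  # fully collapsed
          elems[[length(elems) + 1]] <- c(c1, c2, c3, c4, c5, c6, c7, c8)
          e_body <- c(e_body, body)
          e_layer <- c(e_layer, if (l <= n_layers / 2) "inner" else "outer")
          reg <- if (body == "LV") "LV"
                 else if (k %in% sept_k && k2 %in% c(sept_k, 1L)) "septum"
                 else "RV"
          e_region <- c(e_region, reg)
          e_tab[[length(e_tab) + 1]] <- c(s, k, l)
        }
      }
    }
  }
  elems <- do.call(rbind, elems)
  e_tab <- do.call(rbind, e_tab)
  colnames(e_tab) <- c("slice", "k", "level")

  cavity_faces <- list()
  for (body in names(grids)) {
    g <- grids[[body]]
    K <- loops_meta[[body]]$K
    faces <- list()
    for (s in seq_len(n_s - 1)) {
      for (k in seq_len(K)) {
        k2 <- if (k == K) 1L else k + 1L
        a <- g[s, k, 1]; b <- g[s, k2, 1]
        cc <- g[s + 1, k2, 1]; d <- g[s + 1, k, 1]
        if (a == b || length(unique(c(a, b, cc, d))) < 3) next
        faces[[length(faces) + 1]] <- c(a, b, cc, d)
      }
    }
    cavity_faces[[if (body == "LV") "LV" else "RV"]] <- do.call(rbind, faces)
  }

  basal_nodes <- lapply(grids, function(g) unique(as.vector(g[n_s, , ])))

  mesh <- structure(list(
    nodes = nodes, elems = elems,
    layer = e_layer, region = e_region, body = e_body,
    elem_tab = e_tab, fiber = NULL,
    grids = grids, loops = loops_meta,
    cavity_faces = cavity_faces,
    basal_nodes = basal_nodes,
    n_slices = n_s, n_layers = n_layers, z = z
  ), class = "ventricle_mesh")
  q <- mesh_quality(mesh)
  if (min(q) <= 0)
    stop("meshing produced non-positive Jacobians (self-intersecting contours?)",
         call. = FALSE)
  mesh
}

#' @export
print.ventricle_mesh <- function(x, ...) {
  cat(sprintf("<ventricle_mesh> %d nodes, %d hexahedra (%s), regions: %s\n",
              nrow(x$nodes), nrow(x$elems),
              paste(names(x$grids), collapse = "+"),
              paste(sort(unique(x$region)), collapse = ", ")))
  invisible(x)
}

#' Minimum Jacobian determinant per element at the Gauss points
#'
#' @param mesh A `ventricle_mesh`.
#' @return Numeric vector (one value per element, mm^3 scale).
#' @export
mesh_quality <- function(mesh) {
  element_min_detj(mesh$nodes, mesh$elems)
}

#' Assign layered fiber directions
#'
#' Each element's fiber is the local circumferential direction rotated in
#' the wall tangent plane toward the long axis by the layer- and
#' region-dependent helix angle: LV defaults -60 deg (outer) / +80 deg
#' (inner), RV (including septum) -45 deg / +40 deg, both relative to the
#' circumferential direction. Positive angles tilt toward the base.
#'
#' @param mesh A `ventricle_mesh` with layer and region labels.
#' @param lv_angles,rv_angles Numeric `(outer, inner)` angles in degrees.
#' @return The mesh with an `fiber` M x 3 matrix of unit vectors.
#' @export
assign_fibers <- function(mesh, lv_angles = c(-60, 80),
                          rv_angles = c(-45, 40)) {
  if (is.null(mesh$layer) || is.null(mesh$region))
    stop("mesh lacks layer/region labels", call. = FALSE)
  M <- nrow(mesh$elems)
  fib <- matrix(0, M, 3)
  for (e in seq_len(M)) {
    nd <- mesh$elems[e, ]
    inner_c <- colMeans(mesh$nodes[nd[1:4][c(1, 2)], , drop = FALSE])
    # through-wall direction: level l face (corners 1,5,... ) to level l+1
    lo <- colMeans(mesh$nodes[nd[c(1, 4, 5, 8)], , drop = FALSE])
    hi <- colMeans(mesh$nodes[nd[c(2, 3, 6, 7)], , drop = FALSE])
    nrm <- hi - lo
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-12) { fib[e, ] <- c(1, 0, 0); next }
    nrm <- nrm / nn
    zv <- c(0, 0, 1)
    ec <- c(zv[2] * nrm[3] - zv[3] * nrm[2],
            zv[3] * nrm[1] - zv[1] * nrm[3],
            zv[1] * nrm[2] - zv[2] * nrm[1])
    ecn <- sqrt(sum(ec^2))
    if (ecn < 1e-9) { fib[e, ] <- c(1, 0, 0); next }
    ec <- ec / ecn
    el <- c(nrm[2] * ec[3] - nrm[3] * ec[2],
            nrm[3] * ec[1] - nrm[1] * ec[3],
            nrm[1] * ec[2] - nrm[2] * ec[1])
    ang <- if (mesh$body[e] == "LV") lv_angles else rv_angles
    a <- (if (mesh$layer[e] == "outer") ang[1] else ang[2]) * pi / 180
    v <- cos(a) * ec + sin(a) * el
    fib[e, ] <- v / sqrt(sum(v^2))
  }
  mesh$fiber <- fib
  mesh
}

elem_centroids <- function(mesh) {
  t(vapply(seq_len(nrow(mesh$elems)), function(e)
    colMeans(mesh$nodes[mesh$elems[e, ], , drop = FALSE]), numeric(3)))
}

#' Label scar and patch regions on the RV free wall
#'
#' Regions are specified by an angular extent (degrees, about the long axis)
#' and a range of slice intervals, and are applied through the full wall
#' thickness of the RV free wall.
#'
#' @param mesh A `ventricle_mesh` containing an RV.
#' @param scar_spec,patch_spec Lists `list(center_deg, half_width_deg,
#'   slices)` or `NULL`; `half_width_deg = 0` labels nothing.
#' @return The relabeled mesh.
#' @export
label_regions <- function(mesh, scar_spec = NULL, patch_spec = NULL) {
  if (!"RV" %in% mesh$body) stop("mesh has no RV", call. = FALSE)
  cen <- elem_centroids(mesh)
  phi <- atan2(cen[, 2], cen[, 1]) * 180 / pi
  fw_phi <- range(phi[mesh$region == "RV"])
  sel <- function(spec, what) {
    if (is.null(spec) || spec$half_width_deg <= 0) return(rep(FALSE, nrow(cen)))
    lo <- spec$center_deg - spec$half_width_deg
    hi <- spec$center_deg + spec$half_width_deg
    if (lo < fw_phi[1] - 1e-6 || hi > fw_phi[2] + 1e-6)
      stop(what, " spec lies outside the RV free wall", call. = FALSE)
    mesh$region == "RV" & phi >= lo & phi <= hi &
      mesh$elem_tab[, "slice"] %in% spec$slices
  }
  s_scar <- sel(scar_spec, "scar")
  s_patch <- sel(patch_spec, "patch")
  if (any(s_scar & s_patch))
    stop("scar and patch specifications overlap", call. = FALSE)
  mesh$region[s_scar] <- "scar"
  mesh$region[s_patch] <- "patch"
  mesh
}

#' RV endocardial rings (slice-wise node loops with adjacent elements)
#'
#' @param mesh A `ventricle_mesh` with an RV.
#' @return List per slice: `nodes` (loop node ids), `elements` (inner-layer
#'   element adjacent to each loop segment).
#' @export
rv_endocardial_rings <- function(mesh) {
  if (!"RV" %in% names(mesh$grids)) return(list())
  g <- mesh$grids$RV
  K <- mesh$loops$RV$K
  n_s <- mesh$n_slices
  # map (slice interval, k) -> inner-layer element id
  emap <- new.env(hash = TRUE)
  for (e in which(mesh$body == "RV" & mesh$elem_tab[, "level"] == 1)) {
    emap[[paste(mesh$elem_tab[e, "slice"], mesh$elem_tab[e, "k"])]] <- e
  }
  lapply(seq_len(n_s), function(s) {
    ids <- g[s, , 1]
    keep <- !duplicated(ids)
    si <- min(s, n_s - 1)
    el <- vapply(which(keep), function(k) {
      e <- emap[[paste(si, k)]]
      if (is.null(e)) {
        kk <- k
        while (is.null(e) && kk > 1) { kk <- kk - 1; e <- emap[[paste(si, kk)]] }
        if (is.null(e)) e <- which(mesh$body == "RV")[1]
      }
      e
    }, numeric(1))
    list(nodes = ids[keep], elements = el)
  })
}

# node id on the RV endocardium nearest to angle phi_deg at a slice
rv_surface_node <- function(mesh, phi_deg, slice, side = c("freewall", "septum")) {
  side <- match.arg(side)
  ks <- if (side == "freewall") mesh$loops$RV$freewall_k else mesh$loops$RV$septal_k
  ids <- mesh$grids$RV[slice, ks, 1]
  p <- mesh$nodes[ids, , drop = FALSE]
  ang <- atan2(p[, 2], p[, 1]) * 180 / pi
  ids[which.min(abs(ang - phi_deg))]
}

#' Export a mesh as a legacy ASCII VTK unstructured grid
#'
#' Writes hexahedral cells with cell-data arrays `layer`, `region` (integer
#' codes) and `fiber` (vectors), plus optional point-data displacement.
#'
#' @param mesh A `ventricle_mesh`.
#' @param path Output `.vtk` path.
#' @param disp Optional N x 3 displacement field written as point data.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, disp = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "ventriband mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(mesh$nodes, 1, function(p)
    sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])), con)
  writeLines(sprintf("CELLS %d %d", m, 9 * m), con)
  writeLines(apply(mesh$elems - 1L, 1, function(e)
    paste(c(8, e), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("12", m), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  reg_codes <- c(LV = 0, RV = 1, septum = 2, scar = 3, patch = 4, band = 5)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(reg_codes[mesh$region]), con)
  writeLines(c("SCALARS layer int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(ifelse(mesh$layer == "inner", 0L, 1L)), con)
  if (!is.null(mesh$fiber)) {
    writeLines("VECTORS fiber double", con)
    writeLines(apply(mesh$fiber, 1, function(p)
      sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])), con)
  }
  if (!is.null(disp)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    writeLines("VECTORS displacement double", con)
    writeLines(apply(disp, 1, function(p)
      sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])), con)
  }
  invisible(path)
}
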