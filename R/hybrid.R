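#' Per-section solve dimension map
#'
#' Chemical simulation within a section is either 1D or 3D (this cannot vary
#' by region); each section is set independently and repeated specifications
#' are allowed, with the last one taking effect.
#'
#' @param m morphology.
#' @param ... named arguments or a single named vector/list: section name ->
#'   dimension (1 or 3); alternatively `set_solve_type(m, sections, dimension)`.
#' @param sections character vector of section names.
#' @param dimension 1 or 3 applied to `sections`.
#' @param map an existing map to update (named integer vector).
#' @return named integer vector over all sections (default 1).
#' @export
set_solve_type <- function(m, sections = NULL, dimension = 3L, map = NULL) {
  if (is.null(map)) map <- stats::setNames(rep(1L, length(m$sections)),
                                           names(m$sections))
  if (is.null(sections)) sections <- names(m$sections)
  bad <- setdiff(sections, names(m$sections))
  if (length(bad)) stop("unknown sections: ", paste(bad, collapse = ", "))
  if (!dimension %in% c(1L, 3L)) stop("dimension must be 1 or 3")
  map[sections] <- as.integer(dimension)
  map
}

#' Branched 1D cable diffusion state
#'
#' Per-segment concentrations on the electrical tree with frusta volumes and
#' cross-section coupling areas; implicit (backward Euler) axial diffusion
#' with conservation at branch points and zero-flux ends.
#'
#' @param m segmentized morphology.
#' @param sections sections to include (default all).
#' @param d diffusion constant um^2/ms.
#' @param initial constant (mM) or function `f(sec, x)` of section name and
#'   normalized arc position returning mM.
#' @return an `rxd_cable` with fields `segs` (segment table rows), `u`,
#'   `vol`, and the coupling structure.
#' @export
cable_state <- function(m, sections = names(m$sections), d = 1, initial = 0) {
  if (!isTRUE(m$segmentized)) m <- segmentize(m)
  segs <- m$segments[m$segments$sec %in% sections, , drop = FALSE]
  nid <- seq_len(nrow(segs))
  row_of <- stats::setNames(nid, paste0(segs$sec, "[", segs$seg, "]"))
  # axial couplings: g = D * A / dist between neighboring segment centers
  cpl <- list()
  radius_at <- function(sec, x) {
    s <- m$sections[[sec]]
    arcs <- s$arcs3
    stats::approx(arcs / arcs[length(arcs)], s$points3[, "d"] / 2, xout = x,
                  ties = "ordered")$y
  }
  for (sec in unique(segs$sec)) {
    rows <- which(segs$sec == sec)
    ns <- length(rows)
    if (ns > 1L) {
      for (k in seq_len(ns - 1L)) {
        a <- rows[k]; b <- rows[k + 1L]
        r <- radius_at(sec, segs$x1[a])
        cpl[[length(cpl) + 1L]] <- c(a, b, pi * r^2,
                                     (segs$length[a] + segs$length[b]) / 2)
      }
    }
    par <- m$sections[[sec]]$parent
    if (!is.null(par) && par %in% segs$sec) {
      px <- m$sections[[sec]]$parent_x
      prows <- which(segs$sec == par)
      pseg <- prows[pmin(length(prows),
                         1L + floor(px * length(prows) * (1 - 1e-12)))]
      a <- pseg; b <- rows[1L]
      r <- radius_at(sec, 0)
      cpl[[length(cpl) + 1L]] <- c(a, b, pi * r^2,
                                   (segs$length[a] + segs$length[b]) / 2)
    }
  }
  u <- if (is.function(initial))
    initial(segs$sec, (segs$x0 + segs$x1) / 2) else rep(initial, nrow(segs))
  structure(list(segs = segs, u = u, vol = segs$vol1d, d = d,
                 cpl = do.call(rbind, c(cpl, list(matrix(numeric(), 0, 4))))),
            class = "rxd_cable")
}

#' Implicit 1D diffusion step on the branched cable
#'
#' @param cable an `rxd_cable`.
#' @param dt step, ms.
#' @param nsteps number of steps.
#' @return the advanced cable.
#' @export
step_1d_diffusion <- function(cable, dt, nsteps = 1L) {
  n <- length(cable$u)
  if (!nrow(cable$cpl) || cable$d <= 0 || n == 1L) return(cable)
  g <- cable$d * cable$cpl[, 3] / cable$cpl[, 4]  # um^3/ms
  ia <- cable$cpl[, 1]; ib <- cable$cpl[, 2]
  # (I - dt A) u_new = u, A u|_i = sum g_ij (u_j - u_i) / V_i
  M <- Matrix::sparseMatrix(
    i = c(ia, ib, ia, ib), j = c(ia, ib, ib, ia),
    x = c(dt * g / cable$vol[ia], dt * g / cable$vol[ib],
          -dt * g / cable$vol[ia], -dt * g / cable$vol[ib]),
    dims = c(n, n)) + Matrix::Diagonal(n)
  for (s in seq_len(nsteps))
    cable$u <- as.numeric(Matrix::solve(M, cable$u))
  cable
}

#' Identify 1D-3D junctions
#'
#' For every 3D section whose parent is 1D and every 1D section whose parent
#' is 3D, finds the boundary voxels of the 3D side: stored voxels belonging
#' to the 3D section that intersect the plane perpendicular to the section's
#' end frustum axis at the attachment point. Per boundary voxel the exchange
#' distance is `dx/2 + (1D segment length)/2` and the exchange area is the
#' voxel interior volume raised to the 2/3 power.
#'
#' @param m segmentized morphology.
#' @param map solve-type map from [set_solve_type()].
#' @param grid `rxd_grid` of the 3D sections.
#' @param cable `rxd_cable` of the 1D sections.
#' @return list of junctions: each has `seg1d` (row in the cable), `voxels`,
#'   `dist`, `area`. May be empty when 1D and 3D sections are not contiguous.
#' @export
find_junctions <- function(m, map, grid, cable) {
  if (!isTRUE(m$segmentized)) m <- segmentize(m)
  juncs <- list()
  add_junction <- function(sec3d, end, sec1d, seg1d_idx) {
    s <- m$sections[[sec3d]]
    pts <- s$points3
    np <- nrow(pts)
    if (end == 0L) {
      p <- pts[1L, 1:3]
      ax <- pts[2L, 1:3] - pts[1L, 1:3]
    } else {
      p <- pts[np, 1:3]
      ax <- pts[np, 1:3] - pts[np - 1L, 1:3]
    }
    ax <- ax / sqrt(sum(ax^2))
    segids <- m$segments$id[m$segments$sec == sec3d]
    vox <- which(grid$seg %in% segids)
    if (!length(vox)) return()
    ctr <- voxel_centers(grid)[vox, , drop = FALSE]
    dplane <- (ctr[, 1] - p[1]) * ax[1] + (ctr[, 2] - p[2]) * ax[2] +
      (ctr[, 3] - p[3]) * ax[3]
    # a voxel cube intersects the plane iff the center's plane distance is
    # below the cube's half-extent projected on the normal
    half <- grid$dx / 2 * (abs(ax[1]) + abs(ax[2]) + abs(ax[3]))
    b <- vox[abs(dplane) <= half]
    if (!length(b)) return()
    row1d <- which(cable$segs$sec == sec1d & cable$segs$seg == seg1d_idx)
    if (!length(row1d)) return()
    seglen <- cable$segs$length[row1d]
    juncs[[length(juncs) + 1L]] <<- list(
      seg1d = row1d, voxels = b,
      dist = rep(grid$dx / 2 + seglen / 2, length(b)),
      area = grid$vol[b]^(2 / 3))
  }
  for (nm in names(m$sections)) {
    s <- m$sections[[nm]]
    if (is.null(s$parent)) next
    dim_self <- map[[nm]]; dim_par <- map[[s$parent]]
    if (dim_self == 3L && dim_par == 1L) {
      # 3D child meets 1D parent at the child's 0 end; the 1D boundary
      # segment is the parent segment containing the attachment
      pn <- s$parent
      pseg <- min(m$sections[[pn]]$nseg - 1L,
                  floor(s$parent_x * m$sections[[pn]]$nseg * (1 - 1e-12)))
      add_junction(nm, 0L, pn, pseg)
    } else if (dim_self == 1L && dim_par == 3L) {
      add_junction(s$parent, 1L, nm, 0L)
    }
  }
  juncs
}

#' Fickian exchange fluxes across 1D-3D junctions
#'
#' Computed at the beginning of each timestep, before either domain
#' advances: per boundary voxel the mass flux is
#' `D * area * (c_1D - c_voxel) / dist`, applied with opposite signs to the
#' two sides (the domains are then advanced independently, weakly coupling
#' them).
#'
#' @param junctions from [find_junctions()].
#' @param cable `rxd_cable` (1D side).
#' @param u 3D concentration vector.
#' @param grid `rxd_grid`.
#' @param d diffusion constant um^2/ms.
#' @param dt step, ms.
#' @return list with updated `cable`, `u`, and `dm` (signed voxel mass
#'   transfers, mM um^3; sum of 1D deltas equals minus their total exactly).
#' @export
junction_exchange <- function(junctions, cable, u, grid, d, dt) {
  dm_total <- 0
  for (j in junctions) {
    flux <- d * j$area * (cable$u[j$seg1d] - u[j$voxels]) / j$dist  # mM um^3/ms
    dm <- flux * dt
    u[j$voxels] <- u[j$voxels] + dm / grid$vol[j$voxels]
    cable$u[j$seg1d] <- cable$u[j$seg1d] - sum(dm) / cable$vol[j$seg1d]
    dm_total <- dm_total + sum(dm)
  }
  list(cable = cable, u = u, dm = dm_total)
}

#' Assemble a hybrid 1D-3D model
#'
#' Sections flagged 3D are voxelized; the rest form a branched 1D cable; the
#' two exchange mass at junction voxels every step.
#'
#' @param m morphology (will be segmentized).
#' @param map solve-type map from [set_solve_type()].
#' @param dx,vr,sr voxelization parameters for the 3D subdomain.
#' @param d diffusion constant um^2/ms.
#' @param initial function `f(sec, x)` (mM) applied to both domains, or a
#'   constant.
#' @param dt step, ms.
#' @return an `rxd_hybrid` model.
#' @export
hybrid_model <- function(m, map, dx, d = 1, initial = 0, dt = 0.025,
                         vr = 2L, sr = 1L) {
  if (!isTRUE(m$segmentized)) m <- segmentize(m)
  secs3 <- names(map)[map == 3L]
  secs1 <- names(map)[map == 1L]
  if (!length(secs3)) stop("no 3D sections; use cable_state() directly")
  m3 <- m
  m3$sections <- m$sections[secs3]
  # make the 3D sub-forest self-contained (sever 1D parents)
  for (nm in names(m3$sections)) {
    p <- m3$sections[[nm]]$parent
    # keep an explicit NULL element ($parent <- NULL would remove it and
    # $parent would then partial-match parent_x)
    if (!is.null(p) && !p %in% secs3) m3$sections[[nm]]["parent"] <- list(NULL)
  }
  roots <- names(m3$sections)[vapply(m3$sections, function(s)
    is.null(s$parent), TRUE)]
  grids <- list(); models <- list()
  csg_all <- build_csg(m)  # segment ids from the full morphology
  keep_csg <- function(segids) {
    objs <- Filter(function(o) o$seg %in% segids, csg_all)
    structure(objs, class = "rxd_csg", segments = m$segments)
  }
  # voxelize each connected 3D component on its own grid
  comp_of <- stats::setNames(rep(NA_character_, length(secs3)), secs3)
  for (r in roots) {
    stack <- r
    while (length(stack)) {
      nm <- stack[[1L]]; stack <- stack[-1L]
      comp_of[nm] <- r
      kids <- names(m3$sections)[vapply(m3$sections, function(s)
        identical(s$parent, nm), TRUE)]
      stack <- c(stack, kids)
    }
  }
  ctr_init <- function(grid) {
    if (!is.function(initial)) return(rep(initial, nrow(grid$keys)))
    sec <- m$segments$sec[match(grid$seg, m$segments$id)]
    segrow <- match(grid$seg, m$segments$id)
    xmid <- (m$segments$x0[segrow] + m$segments$x1[segrow]) / 2
    initial(sec, xmid)
  }
  comps <- list()
  for (r in roots) {
    secs <- names(comp_of)[comp_of == r]
    segids <- m$segments$id[m$segments$sec %in% secs]
    grid <- voxelize(keep_csg(segids), dx, vr = vr, sr = sr)
    comps[[r]] <- list(grid = grid, lines = build_lines(grid),
                       u = ctr_init(grid), secs = secs)
  }
  cable <- if (length(secs1))
    cable_state(m, sections = secs1, d = d, initial = initial) else NULL
  juncs <- list()
  if (!is.null(cable)) {
    for (r in names(comps)) {
      jj <- find_junctions(m, map, comps[[r]]$grid, cable)
      juncs[[r]] <- jj
    }
  }
  structure(list(m = m, map = map, comps = comps, cable = cable,
                 junctions = juncs, d = d, dt = dt, t = 0),
            class = "rxd_hybrid")
}

#' Advance a hybrid model one (or more) steps
#'
#' Order within each step: junction exchange, then the 1D cable advance,
#' then each 3D component (reactions would precede DG-ADI; the hybrid
#' validation models are pure diffusion).
#'
#' @param model an `rxd_hybrid`.
#' @param nsteps number of dt-steps.
#' @return the advanced model.
#' @export
hybrid_step <- function(model, nsteps = 1L) {
  for (s in seq_len(nsteps)) {
    if (!is.null(model$cable)) {
      for (r in names(model$comps)) {
        ex <- junction_exchange(model$junctions[[r]], model$cable,
                                model$comps[[r]]$u, model$comps[[r]]$grid,
                                model$d, model$dt)
        model$cable <- ex$cable
        model$comps[[r]]$u <- ex$u
      }
      model$cable <- step_1d_diffusion(model$cable, model$dt)
    }
    for (r in names(model$comps)) {
      cm <- model$comps[[r]]
      model$comps[[r]]$u <- dg_adi_step(cm$u, cm$grid, cm$lines, model$d,
                                        model$dt)
    }
    model$t <- model$t + model$dt
  }
  model
}

#' Total mass of a hybrid model (mM um^3)
#' @param model an `rxd_hybrid`.
#' @return total mass in mM um^3.
#' @export
hybrid_mass <- function(model) {
  m <- if (!is.null(model$cable)) sum(model$cable$u * model$cable$vol) else 0
  for (r in names(model$comps))
    m <- m + sum(model$comps[[r]]$u * model$comps[[r]]$grid$vol)
  m
}

#' Volume-weighted concentration profile at the 1D node positions
#'
#' The 3D domain reports, per electrical segment, the volume-weighted mean
#' concentration over the segment's voxels (the per-node quantity fed back
#' to 1D mechanisms; thin surface-sliver layers at a domain edge are pooled
#' with the full layers of the segment that owns them); 1D segments report
#' their concentration directly. Positions are the segment centers. Used to
#' compare hybrid and pure runs against the closed-form solution.
#'
#' @param model an `rxd_hybrid`.
#' @return data.frame with `x`, `conc`, `domain`.
#' @export
hybrid_profile <- function(model) {
  segs <- model$m$segments
  seg_x <- function(rows) {
    mapply(function(sec, x0, x1) {
      s <- model$m$sections[[sec]]
      arcs <- s$arcs3
      xm <- (x0 + x1) / 2 * arcs[length(arcs)]
      stats::approx(arcs, s$points3[, "x"], xout = xm, ties = "ordered")$y
    }, segs$sec[rows], segs$x0[rows], segs$x1[rows])
  }
  out <- list()
  for (r in names(model$comps)) {
    g <- model$comps[[r]]$grid
    u <- model$comps[[r]]$u
    fb <- segment_feedback(g, u, mode = "all")
    rows <- as.integer(names(fb))
    ok <- !is.na(fb)
    out[[length(out) + 1L]] <- data.frame(
      x = as.numeric(seg_x(rows[ok])), conc = as.numeric(fb[ok]),
      domain = "3d", stringsAsFactors = FALSE)
  }
  if (!is.null(model$cable)) {
    sgs <- model$cable$segs
    # segment center x assuming sections run along the x axis (fixtures)
    ctr <- mapply(function(sec, x0, x1) {
      s <- model$m$sections[[sec]]
      arcs <- s$arcs3
      xm <- (x0 + x1) / 2 * arcs[length(arcs)]
      stats::approx(arcs, s$points3[, "x"], xout = xm, ties = "ordered")$y
    }, sgs$sec, sgs$x0, sgs$x1)
    out[[length(out) + 1L]] <- data.frame(x = as.numeric(ctr),
                                          conc = model$cable$u,
                                          domain = "1d",
                                          stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$x), ]
}
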