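# Sparse voxelization of CSG unions.
#
# Voxels live on an imaginary padded bounding-box grid with edge dx and are
# stored sparsely (memory proportional to the cell volume, not the bounding
# box). A voxel is stored iff at least one of its 8 corners lies inside the
# union of objects; it is a surface voxel iff at least one corner also lies
# outside. Corner signed distances (min over objects, i.e. the union's
# signed distance) drive marching-cubes surface areas; surface-voxel volume
# fractions come from counting test points on a (1+VR)^3 corner-to-corner
# lattice, points on the boundary counting as inside.

MC_ENC <- 131072  # 2^17; grid index encoder base (exact in doubles up to 2^51)

# "inside" means signed distance <= this tolerance (um). Points exactly on
# the boundary count as inside; the tolerance additionally absorbs the
# ~1e-16 jitter between an object and its axial chunks when a surface
# passes exactly through lattice corners.
INSIDE_TOL <- 1e-9

enc_key <- function(i, j, k) i + MC_ENC * (j + MC_ENC * k)
dec_key <- function(e) {
  i <- e %% MC_ENC
  e <- (e - i) / MC_ENC
  j <- e %% MC_ENC
  k <- (e - j) / MC_ENC
  cbind(i = i, j = j, k = k)
}

#' Grid parameters for voxelization
#'
#' @param dx voxel edge, micrometers.
#' @param vr partial-volume resolution: surface-voxel volume fractions are
#'   estimated from `(1+vr)^3` test points per voxel (default 2).
#' @param sr partial-surface resolution: marching-cubes runs on `sr^3`
#'   subcells per surface voxel (default 1).
#' @param pad padding of the bounding box, in voxels, on every side.
#' @export
grid_params <- function(dx, vr = 2L, sr = 1L, pad = 2L) {
  stopifnot(dx > 0, vr >= 1L, sr >= 1L, pad >= 0L)
  list(dx = dx, vr = as.integer(vr), sr = as.integer(sr), pad = as.integer(pad))
}

csg_global_origin <- function(csg, params) {
  lo <- Reduce(pmin, lapply(csg, function(o) o$aabb[1, ]))
  (floor(lo / params$dx) - params$pad) * params$dx
}

# Split long frusta into axial chunks so each local dense corner grid stays
# small and hugs the solid (pure geometry split; same union).
chunk_object <- function(obj, dx) {
  if (obj$type != "frustum") return(list(obj))
  max_len <- max(20 * dx, 2 * max(obj$r0, obj$r1))
  if (obj$L <= max_len) return(list(obj))
  nch <- ceiling(obj$L / max_len)
  ts <- seq(0, 1, length.out = nch + 1L)
  lapply(seq_len(nch), function(c8) {
    t0 <- ts[c8]; t1 <- ts[c8 + 1L]
    csg_frustum(obj$p0 + t0 * (obj$p1 - obj$p0),
                obj$p0 + t1 * (obj$p1 - obj$p0),
                obj$r0 + t0 * (obj$r1 - obj$r0),
                obj$r0 + t1 * (obj$r1 - obj$r0), obj$seg)
  })
}

# Corner coordinate vectors for an index range (corners at origin + idx*dx)
corner_seq <- function(i0, i1, origin, dx) origin + (i0:i1) * dx

#' Voxelize a single convex CSG object
#'
#' Finds every stored voxel of one object by evaluating its signed distance
#' on the corner lattice of the object's padded bounding box (the dense
#' equivalent, for a convex solid, of propagating voxel rows from a seed and
#' filling between row endpoints). Voxels with 1-7 inside corners are the
#' object's surface voxels.
#'
#' @param obj a CSG object (see [build_csg()]).
#' @param params [grid_params()].
#' @param origin grid origin (pass the morphology-wide origin so parts can be
#'   merged; defaults to the object's own snapped origin).
#' @param bounds optional 2x3 matrix of global grid corner-index bounds used
#'   to clip (objects outside yield an empty part).
#' @return a partial voxel set: list with `keys` (n x 3 integer matrix),
#'   `ninside` (corner counts), `seg` (owning segment id).
#' @export
voxelize_object <- function(obj, params, origin = NULL, bounds = NULL) {
  dx <- params$dx
  if (is.null(origin)) origin <- csg_global_origin(list(obj), params)
  empty <- list(keys = matrix(integer(), 0, 3), ninside = integer(),
                seg = obj$seg)
  i0 <- floor((obj$aabb[1, ] - origin) / dx) - 1
  i1 <- ceiling((obj$aabb[2, ] - origin) / dx) + 1
  if (!is.null(bounds)) {
    i0 <- pmax(i0, bounds[1, ]); i1 <- pmin(i1, bounds[2, ])
  } else i0 <- pmax(i0, 0)
  if (any(i1 <= i0)) return(empty)
  nx <- i1[1] - i0[1] + 1; ny <- i1[2] - i0[2] + 1; nz <- i1[3] - i0[3] + 1
  xs <- corner_seq(i0[1], i1[1], origin[1], dx)
  ys <- corner_seq(i0[2], i1[2], origin[2], dx)
  zs <- corner_seq(i0[3], i1[3], origin[3], dx)
  px <- rep(xs, times = ny * nz)
  py <- rep(rep(ys, each = nx), times = nz)
  pz <- rep(zs, each = nx * ny)
  ins <- array(csg_sdf(obj, px, py, pz) <= INSIDE_TOL, dim = c(nx, ny, nz))
  sub <- function(di, dj, dk)
    ins[(1 + di):(nx - 1 + di), (1 + dj):(ny - 1 + dj), (1 + dk):(nz - 1 + dk),
        drop = FALSE]
  cnt <- sub(0,0,0) + sub(1,0,0) + sub(0,1,0) + sub(0,0,1) +
         sub(1,1,0) + sub(1,0,1) + sub(0,1,1) + sub(1,1,1)
  w <- which(cnt >= 1L)
  if (!length(w)) return(empty)
  loc <- arrayInd(w, dim(cnt))
  keys <- cbind(loc[, 1] - 1L + as.integer(i0[1]),
                loc[, 2] - 1L + as.integer(i0[2]),
                loc[, 3] - 1L + as.integer(i0[3]))
  list(keys = keys, ninside = as.integer(cnt[w]), seg = obj$seg)
}

#' Merge partial voxel sets into a voxel grid
#'
#' Takes the union of the parts' voxels; overlapping voxels are assigned to
#' the owning segment closest to the root of the electrophysiological tree.
#' Corner signed distances are recombined as the minimum over all objects
#' (the union's signed distance), the surface flag is recomputed from the
#' union (a voxel is surface only if a corner remains outside the union),
#' and surface-voxel volume fractions and marching-cubes areas are computed
#' against the union.
#'
#' @param parts list of partial voxel sets from [voxelize_object()]
#'   (all on the same grid/origin).
#' @param csg the CSG object list the parts came from.
#' @param params [grid_params()].
#' @param origin shared grid origin.
#' @param segments segment table (`attr(csg, "segments")` by default),
#'   used for the root-closest ownership rule.
#' @return an object of class `rxd_grid`.
#' @export
merge_meshes <- function(parts, csg, params, origin,
                         segments = attr(csg, "segments")) {
  dx <- params$dx
  keys <- do.call(rbind, lapply(parts, `[[`, "keys"))
  if (is.null(keys) || !nrow(keys)) stop("empty grid: no voxels stored")
  enc <- enc_key(keys[, 1], keys[, 2], keys[, 3])
  uenc <- sort(unique(enc))
  n <- length(uenc)
  ukeys <- dec_key(uenc)

  # segment ownership: min root-path distance wins
  segsrc <- unlist(lapply(parts, function(p) rep(p$seg, nrow(p$keys))))
  rootd <- segments$path_center[match(segsrc, segments$id)]
  o <- order(enc, rootd)
  first <- !duplicated(enc[o])
  seg <- integer(n)
  seg[match(enc[o][first], uenc)] <- segsrc[o][first]

  # union signed distance on the corner lattice of stored voxels
  off <- mc_corner_off
  cenc_all <- as.vector(vapply(1:8, function(c8)
    enc_key(ukeys[, 1] + off[c8, 1], ukeys[, 2] + off[c8, 2],
            ukeys[, 3] + off[c8, 3]), numeric(n)))
  cenc <- sort(unique(cenc_all))
  ckeys <- dec_key(cenc)
  cx <- origin[1] + ckeys[, 1] * dx
  cy <- origin[2] + ckeys[, 2] * dx
  cz <- origin[3] + ckeys[, 3] * dx
  cdist <- rep(Inf, length(cenc))
  for (obj in csg) {
    lo <- obj$aabb[1, ] - dx; hi <- obj$aabb[2, ] + dx
    sel <- which(cx >= lo[1] & cx <= hi[1] & cy >= lo[2] & cy <= hi[2] &
                 cz >= lo[3] & cz <= hi[3])
    if (!length(sel)) next
    cdist[sel] <- pmin(cdist[sel], csg_sdf(obj, cx[sel], cy[sel], cz[sel]))
  }

  cidx <- matrix(0L, n, 8L)
  for (c8 in 1:8) {
    e <- enc_key(ukeys[, 1] + off[c8, 1], ukeys[, 2] + off[c8, 2],
                 ukeys[, 3] + off[c8, 3])
    cidx[, c8] <- findInterval(e, cenc)
  }
  cd <- matrix(cdist[cidx], n, 8L)
  nin <- rowSums(cd <= INSIDE_TOL)
  if (any(nin == 0L)) {
    # round-off slivers: candidates whose corners all fall outside the
    # union (possible when a surface passes exactly through corners)
    keep <- nin > 0L
    uenc <- uenc[keep]; ukeys <- ukeys[keep, , drop = FALSE]
    seg <- seg[keep]; cd <- cd[keep, , drop = FALSE]
    nin <- nin[keep]; n <- sum(keep)
  }
  surface <- nin < 8L

  grid <- structure(list(
    dx = dx, vr = params$vr, sr = params$sr, pad = params$pad,
    origin = origin, keys = ukeys, enc = uenc, seg = seg,
    surface = surface, corner_dist = cd, csg = csg, segments = segments),
    class = "rxd_grid")
  grid$frac <- partial_volumes(grid, params$vr)
  grid$vol <- grid$frac * dx^3
  grid$area <- surface_areas(grid, params$sr)
  grid$totals <- list(volume = sum(grid$vol), area = sum(grid$area))
  grid
}

#' Voxelize a morphology or CSG list
#'
#' Convenience wrapper: builds the CSG union (for a morphology), voxelizes
#' each object separately (exploiting convexity), and merges the parts.
#'
#' @param x an `rxd_morphology` or `rxd_csg`.
#' @param dx voxel edge, micrometers.
#' @param vr,sr,pad see [grid_params()].
#' @return an `rxd_grid`; see [merge_meshes()] for the fields.
#' @export
voxelize <- function(x, dx, vr = 2L, sr = 1L, pad = 2L) {
  params <- grid_params(dx, vr, sr, pad)
  csg <- if (inherits(x, "rxd_csg")) x else build_csg(x)
  if (!length(csg)) stop("empty CSG: nothing to voxelize")
  origin <- csg_global_origin(csg, params)
  parts <- list()
  for (obj in csg) {
    for (ch in chunk_object(obj, dx)) {
      parts[[length(parts) + 1L]] <- voxelize_object(ch, params, origin)
    }
  }
  merge_meshes(parts, csg, params, origin)
}

#' Surface-voxel volume fractions
#'
#' Fraction of `(1+vr)^3` uniformly spaced test points (corner to corner)
#' inside the union; test points exactly on the boundary count as inside.
#' Interior voxels return 1 exactly; the fraction of a stored voxel is never
#' 0 because at least one corner is inside.
#'
#' @param grid an `rxd_grid`.
#' @param vr partial-volume resolution.
#' @return numeric vector of fractions in `(0, 1]`, one per stored voxel.
#' @export
partial_volumes <- function(grid, vr = grid$vr) {
  n <- nrow(grid$keys)
  frac <- rep(1, n)
  sv <- which(grid$surface)
  if (!length(sv)) return(frac)
  if (vr == 1L) {
    frac[sv] <- rowSums(grid$corner_dist[sv, , drop = FALSE] <= INSIDE_TOL) / 8
    return(frac)
  }
  dx <- grid$dx
  g <- seq(0, 1, length.out = vr + 1L)
  npt <- (vr + 1L)^3
  offs <- as.matrix(expand.grid(gx = g, gy = g, gz = g))
  ns <- length(sv)
  px <- rep(grid$origin[1] + grid$keys[sv, 1] * dx, times = npt) +
    rep(offs[, 1] * dx, each = ns)
  py <- rep(grid$origin[2] + grid$keys[sv, 2] * dx, times = npt) +
    rep(offs[, 2] * dx, each = ns)
  pz <- rep(grid$origin[3] + grid$keys[sv, 3] * dx, times = npt) +
    rep(offs[, 3] * dx, each = ns)
  dist <- rep(Inf, ns * npt)
  for (obj in grid$csg) {
    lo <- obj$aabb[1, ]; hi <- obj$aabb[2, ]
    sel <- which(px >= lo[1] & px <= hi[1] & py >= lo[2] & py <= hi[2] &
                 pz >= lo[3] & pz <= hi[3])
    if (!length(sel)) next
    dist[sel] <- pmin(dist[sel], csg_sdf(obj, px[sel], py[sel], pz[sel]))
  }
  cnt <- rowSums(matrix(dist <= INSIDE_TOL, ns, npt))
  frac[sv] <- pmax(cnt, 1L) / npt  # never zero: >=1 corner is inside
  frac
}

#' Per-voxel marching-cubes surface areas
#'
#' Triangulates the union isosurface within each surface voxel from its
#' corner signed distances (linear interpolation along edges; `sr^3`
#' trilinearly interpolated subcells when `sr > 1`) and sums triangle areas.
#' Interior voxels have area 0. Voxels whose computed area is exactly zero
#' remain stored but should not be used for surface-based kinetics.
#'
#' @param grid an `rxd_grid`.
#' @param sr partial-surface resolution.
#' @return numeric vector of areas (um^2) per stored voxel.
#' @export
surface_areas <- function(grid, sr = grid$sr) {
  n <- nrow(grid$keys)
  area <- numeric(n)
  sv <- which(grid$surface)
  if (length(sv))
    area[sv] <- mc_areas_sr(grid$corner_dist[sv, , drop = FALSE], sr) * grid$dx^2
  area
}

#' @export
print.rxd_grid <- function(x, ...) {
  cat(sprintf(paste0("<rxd_grid> %d voxels (%d surface), dx=%g um, VR=%d, ",
                     "SR=%d\n  volume %.4f um^3, surface area %.4f um^2\n"),
              nrow(x$keys), sum(x$surface), x$dx, x$vr, x$sr,
              x$totals$volume, x$totals$area))
  invisible(x)
}

#' Voxel centers in physical coordinates
#' @param grid an `rxd_grid`.
#' @return n x 3 matrix of voxel center coordinates (um).
#' @export
voxel_centers <- function(grid) {
  sweep((grid$keys + 0.5) * grid$dx, 2, grid$origin, `+`)
}

#' Look up the stored voxel containing a point
#' @param grid an `rxd_grid`.
#' @param p numeric length-3 point or n x 3 matrix (um).
#' @return integer storage indices (NA when the point's voxel is not stored).
#' @export
voxel_at <- function(grid, p) {
  p <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  ijk <- floor(sweep(p, 2, grid$origin) / grid$dx)
  e <- enc_key(ijk[, 1], ijk[, 2], ijk[, 3])
  i <- findInterval(e, grid$enc)
  i[i < 1L] <- NA_integer_
  ok <- !is.na(i) & grid$enc[pmax(i, 1L)] == e
  i[!ok] <- NA_integer_
  i
}
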