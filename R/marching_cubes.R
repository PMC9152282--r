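# Marching cubes surface-area estimation from corner signed distances.
#
# The classic case table is built once, programmatically, from the cube's
# combinatorics: on every cube face the crossing edges are paired (a face
# with four crossings is ambiguous and is resolved by the fixed convention
# that the two diagonally-opposite inside corners are kept separate); each
# crossing edge lies on two faces and so receives exactly two pairings,
# whose union decomposes into closed polygons that are fan-triangulated.
# This reproduces the standard 15-case (asymptotic-decider-free) surface.

# corner numbering (standard MC): 1:(0,0,0) 2:(1,0,0) 3:(1,1,0) 4:(0,1,0)
#                                 5:(0,0,1) 6:(1,0,1) 7:(1,1,1) 8:(0,1,1)
mc_corner_off <- matrix(c(0,0,0, 1,0,0, 1,1,0, 0,1,0,
                          0,0,1, 1,0,1, 1,1,1, 0,1,1),
                        ncol = 3, byrow = TRUE)
mc_edges <- matrix(c(1,2, 2,3, 3,4, 4,1,
                     5,6, 6,7, 7,8, 8,5,
                     1,5, 2,6, 3,7, 4,8), ncol = 2, byrow = TRUE)
# faces as cyclic corner sequences
mc_faces <- list(c(1,2,3,4), c(5,6,7,8), c(1,2,6,5),
                 c(2,3,7,6), c(3,4,8,7), c(4,1,5,8))

mc_edge_lookup <- local({
  m <- matrix(0L, 8, 8)
  for (e in seq_len(nrow(mc_edges))) {
    m[mc_edges[e, 1], mc_edges[e, 2]] <- e
    m[mc_edges[e, 2], mc_edges[e, 1]] <- e
  }
  m
})

mc_build_case <- function(inside) {
  # inside: logical[8]; returns matrix of triangles (rows of 3 edge indices)
  links <- vector("list", 12L)  # per crossing edge: the two linked edges
  for (f in mc_faces) {
    fe <- integer(); fc <- integer()
    for (m in 1:4) {
      a <- f[m]; b <- f[m %% 4 + 1]
      if (inside[a] != inside[b]) {
        fe <- c(fe, mc_edge_lookup[a, b]); fc <- c(fc, m)
      }
    }
    if (length(fe) == 0L) next
    if (length(fe) == 2L) {
      pairs <- list(fe)
    } else {
      # ambiguous face: pair the two crossing edges adjacent to each inside
      # corner, keeping the diagonal inside corners separate
      pairs <- list()
      for (m in 1:4) {
        if (!inside[f[m]]) next
        e_prev <- mc_edge_lookup[f[(m - 2) %% 4 + 1], f[m]]
        e_next <- mc_edge_lookup[f[m], f[m %% 4 + 1]]
        pairs[[length(pairs) + 1L]] <- c(e_prev, e_next)
      }
    }
    for (pr in pairs) {
      links[[pr[1]]] <- c(links[[pr[1]]], pr[2])
      links[[pr[2]]] <- c(links[[pr[2]]], pr[1])
    }
  }
  crossing <- which(lengths(links) > 0)
  tri <- matrix(integer(), 0, 3)
  visited <- logical(12L)
  for (e0 in crossing) {
    if (visited[e0]) next
    poly <- e0; visited[e0] <- TRUE
    prev <- 0L; cur <- e0
    repeat {
      nxt <- setdiff(links[[cur]], prev)[1]
      if (is.na(nxt) || nxt == e0) break
      poly <- c(poly, nxt); visited[nxt] <- TRUE
      prev <- cur; cur <- nxt
    }
    if (length(poly) >= 3L) {
      for (k in 2:(length(poly) - 1L))
        tri <- rbind(tri, c(poly[1], poly[k], poly[k + 1]))
    }
  }
  tri
}

mc_table_env <- new.env(parent = emptyenv())

mc_case_table <- function() {
  if (!is.null(mc_table_env$tab)) return(mc_table_env$tab)
  tab <- vector("list", 256L)
  for (code in 0:255) {
    inside <- as.logical(bitwAnd(code, bitwShiftL(1L, 0:7)))
    tab[[code + 1L]] <- mc_build_case(inside)
  }
  mc_table_env$tab <- tab
  tab
}

# Triangulated surface areas for voxels given their 8 corner signed
# distances (rows of `cd`, corners in mc order, negative inside). Vectorized
# by grouping voxels with the same sign pattern. Returns area in units of
# edge^2 (multiply by dx^2 for physical area).
mc_areas <- function(cd) {
  n <- nrow(cd)
  if (!n) return(numeric())
  inside <- cd <= INSIDE_TOL
  code <- as.integer(inside %*% 2^(0:7))
  if (any(code == 0L | code == 255L))
    stop("marching cubes: voxel ", which(code == 0L | code == 255L)[1],
         " has all corners on the same side of the surface")
  tab <- mc_case_table()
  area <- numeric(n)
  for (cs in unique(code)) {
    tri <- tab[[cs + 1L]]
    if (!nrow(tri)) next
    sel <- which(code == cs)
    d <- cd[sel, , drop = FALSE]
    # crossing point on each needed edge, coordinates in [0,1]^3
    edges_needed <- sort(unique(as.vector(tri)))
    vx <- vy <- vz <- matrix(NA_real_, length(sel), 12L)
    for (e in edges_needed) {
      a <- mc_edges[e, 1]; b <- mc_edges[e, 2]
      t <- d[, a] / (d[, a] - d[, b])
      vx[, e] <- mc_corner_off[a, 1] + t * (mc_corner_off[b, 1] - mc_corner_off[a, 1])
      vy[, e] <- mc_corner_off[a, 2] + t * (mc_corner_off[b, 2] - mc_corner_off[a, 2])
      vz[, e] <- mc_corner_off[a, 3] + t * (mc_corner_off[b, 3] - mc_corner_off[a, 3])
    }
    for (k in seq_len(nrow(tri))) {
      e1 <- tri[k, 1]; e2 <- tri[k, 2]; e3 <- tri[k, 3]
      ux <- vx[, e2] - vx[, e1]; uy <- vy[, e2] - vy[, e1]; uz <- vz[, e2] - vz[, e1]
      wx <- vx[, e3] - vx[, e1]; wy <- vy[, e3] - vy[, e1]; wz <- vz[, e3] - vz[, e1]
      cxv <- uy * wz - uz * wy; cyv <- uz * wx - ux * wz; czv <- ux * wy - uy * wx
      area[sel] <- area[sel] + 0.5 * sqrt(cxv^2 + cyv^2 + czv^2)
    }
  }
  area
}

# Subdivided marching cubes: split each voxel into SR^3 subcells with
# trilinearly interpolated corner values, run mc on subcells that straddle
# the surface. Area in units of (voxel edge)^2.
mc_areas_sr <- function(cd, sr) {
  if (sr <= 1L) return(mc_areas(cd))
  n <- nrow(cd)
  area <- numeric(n)
  g <- seq(0, 1, length.out = sr + 1L)
  interp <- function(px, py, pz) {
    # trilinear interpolation of the 8 corner values at (px,py,pz)
    cd[, 1] * (1-px)*(1-py)*(1-pz) + cd[, 2] * px*(1-py)*(1-pz) +
    cd[, 3] * px*py*(1-pz)         + cd[, 4] * (1-px)*py*(1-pz) +
    cd[, 5] * (1-px)*(1-py)*pz     + cd[, 6] * px*(1-py)*pz +
    cd[, 7] * px*py*pz             + cd[, 8] * (1-px)*py*pz
  }
  for (i in seq_len(sr)) for (j in seq_len(sr)) for (k in seq_len(sr)) {
    sub <- matrix(NA_real_, n, 8L)
    for (c8 in 1:8) {
      sub[, c8] <- interp(g[i + mc_corner_off[c8, 1]],
                          g[j + mc_corner_off[c8, 2]],
                          g[k + mc_corner_off[c8, 3]])
    }
    straddle <- rowSums(sub <= INSIDE_TOL) %in% 1:7
    if (any(straddle))
      area[straddle] <- area[straddle] +
        mc_areas(sub[straddle, , drop = FALSE]) / sr^2
  }
  area
}
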