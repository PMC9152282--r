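#' Constructive solid geometry for neuron volumes
#'
#' The 3D volume of a cell is the union of cone frusta (one per consecutive
#' point-diameter pair) and join spheres clipped by planes, each owned by one
#' electrical segment. Signed distances are negative inside.
#'
#' @name csg
NULL

csg_frustum <- function(p0, p1, r0, r1, seg) {
  a <- p1 - p0
  L <- sqrt(sum(a * a))
  if (L <= 0) return(NULL)
  structure(list(type = "frustum", p0 = p0, p1 = p1, r0 = r0, r1 = r1,
                 axis = a / L, L = L, seg = seg,
                 aabb = rbind(pmin(p0 - r0, p1 - r1), pmax(p0 + r0, p1 + r1))),
            class = "rxd_csg_obj")
}

csg_sphere <- function(center, r, clips = list(), seg) {
  structure(list(type = "sphere", center = center, r = r, clips = clips,
                 seg = seg, aabb = rbind(center - r, center + r)),
            class = "rxd_csg_obj")
}

#' Signed distance of points to a CSG object
#'
#' Negative inside the solid, positive outside.
#' A frustum is a solid of revolution, so its exact Euclidean signed distance
#' equals the 2D signed distance, in the (axial, radial) half-plane, to the
#' generating trapezoid with corners (0,0), (0,r0), (L,r1), (L,0): inside,
#' minus the smallest perpendicular face distance; outside, the distance to
#' the nearest of the three boundary edges (lateral and two caps). A clipped
#' sphere takes the max of the sphere distance and the clip-plane distances
#' (exact inside; a tight underestimate outside near clip edges).
#'
#' @param obj a CSG object from [build_csg()].
#' @param x,y,z point coordinate vectors, um.
#' @return signed distances, um.
#' @export
csg_sdf <- function(obj, x, y, z) {
  if (obj$type == "frustum") {
    qx <- x - obj$p0[1]; qy <- y - obj$p0[2]; qz <- z - obj$p0[3]
    t <- qx * obj$axis[1] + qy * obj$axis[2] + qz * obj$axis[3]
    rad2 <- qx * qx + qy * qy + qz * qz - t * t
    rad2[rad2 < 0] <- 0
    rho <- sqrt(rad2)
    dr <- obj$r1 - obj$r0
    len <- sqrt(obj$L^2 + dr^2)
    s_lat <- (rho - (obj$r0 + dr * t / obj$L)) * (obj$L / len)
    inside <- s_lat <= 0 & t >= 0 & t <= obj$L
    d <- numeric(length(t))
    d[inside] <- -pmin(-s_lat[inside], t[inside], obj$L - t[inside])
    out <- !inside
    if (any(out)) {
      to <- t[out]; ro <- rho[out]
      seg_dist <- function(ax_, ay_, bx_, by_) {
        vx_ <- bx_ - ax_; vy_ <- by_ - ay_
        tt <- pmin(1, pmax(0, ((to - ax_) * vx_ + (ro - ay_) * vy_) /
                              (vx_^2 + vy_^2)))
        sqrt((to - (ax_ + tt * vx_))^2 + (ro - (ay_ + tt * vy_))^2)
      }
      d[out] <- pmin(seg_dist(0, obj$r0, obj$L, obj$r1),   # lateral
                     seg_dist(0, 0, 0, obj$r0),            # cap at t = 0
                     seg_dist(obj$L, 0, obj$L, obj$r1))    # cap at t = L
    }
    d
  } else {
    d <- sqrt((x - obj$center[1])^2 + (y - obj$center[2])^2 +
              (z - obj$center[3])^2) - obj$r
    for (cl in obj$clips) {
      d <- pmax(d, (x - cl$p[1]) * cl$n[1] + (y - cl$p[2]) * cl$n[2] +
                   (z - cl$p[3]) * cl$n[3])
    }
    d
  }
}

# TRUE when a clipped sphere is empty or measure-zero (clip planes through
# the center with opposing normals, i.e. collinear adjacent frusta).
sphere_clipped_empty <- function(obj) {
  if (length(obj$clips) < 2L) return(FALSE)
  for (i in seq_along(obj$clips)) {
    for (j in seq_along(obj$clips)) {
      if (i >= j) next
      ni <- obj$clips[[i]]$n; nj <- obj$clips[[j]]$n
      # keep regions n.(x-p) <= 0; opposing normals through the same point
      if (sum(ni * nj) < -1 + 1e-9 &&
          sum(abs(obj$clips[[i]]$p - obj$clips[[j]]$p)) < 1e-9)
        return(TRUE)
    }
  }
  FALSE
}

#' Build the CSG object list for a morphology
#'
#' One frustum per consecutive point pair (after segment-boundary
#' interpolation, so every frustum belongs to exactly one segment). Interior
#' polyline points and end-attachments of child sections receive join spheres
#' of radius equal to the shared sample radius (end attachments: the larger
#' of the two adjacent end radii), clipped to the wedge between the adjacent
#' end-face planes; for collinear joins the wedge is empty and the sphere is
#' dropped (it adds no volume). Where a child attaches at a parent's end with
#' a different diameter, a connection cone is added from the attachment point
#' (parent end radius) to the midpoint of the child's first segment (child
#' radius), smoothing abrupt diameter changes. Children attaching at interior
#' positions (spines) get no join objects; with `pt3d_style` their first
#' point is taken as given, otherwise it lies on the parent centroid.
#'
#' @param m morphology; segmentized automatically if needed.
#' @return list of CSG objects (class `rxd_csg`), each carrying the id of the
#'   owning segment; degenerate zero-length frusta are dropped silently.
#' @export
build_csg <- function(m) {
  if (!isTRUE(m$segmentized)) m <- segmentize(m)
  objs <- list()
  add <- function(o) if (!is.null(o)) objs[[length(objs) + 1L]] <<- o
  for (nm in topo_order(m)) {
    s <- m$sections[[nm]]
    pts <- s$points3; r <- pts[, "d"] / 2; np <- nrow(pts)
    fseg <- s$frustum_seg
    axes <- diff(pts[, 1:3, drop = FALSE])
    lens <- sqrt(rowSums(axes^2))
    axes <- axes / lens
    for (i in seq_len(np - 1L)) {
      if (lens[i] <= 0) next
      add(csg_frustum(pts[i, 1:3], pts[i + 1L, 1:3], r[i], r[i + 1L],
                      segment_id(m, nm, fseg[i])))
    }
    # interior joins
    for (i in (if (np > 2L) 2:(np - 1L) else integer())) {
      if (sum(axes[i - 1L, ] * axes[i, ]) > 1 - 1e-12) next  # collinear
      sp <- csg_sphere(pts[i, 1:3], r[i],
                       clips = list(list(p = pts[i, 1:3], n = -axes[i - 1L, ]),
                                    list(p = pts[i, 1:3], n = axes[i, ])),
                       seg = segment_id(m, nm, fseg[i - 1L]))
      if (!sphere_clipped_empty(sp)) add(sp)
    }
    # attachment joins to the parent (end attachments only; spines attach
    # at interior positions and need no join)
    if (!is.null(s$parent) && !s$pt3d_style && s$parent_x > 1 - 1e-9) {
      p <- m$sections[[s$parent]]
      ppts <- p$points3; pr <- ppts[, "d"] / 2; pnp <- nrow(ppts)
      pax <- ppts[pnp, 1:3] - ppts[pnp - 1L, 1:3]
      pax <- pax / sqrt(sum(pax^2))
      attach_pt <- ppts[pnp, 1:3]
      r_par <- pr[pnp]; r_child <- r[1L]
      cax <- axes[1L, ]
      if (sum(pax * cax) <= 1 - 1e-12) {
        sp <- csg_sphere(attach_pt, max(r_par, r_child),
                         clips = list(list(p = attach_pt, n = -pax),
                                      list(p = attach_pt, n = cax)),
                         seg = segment_id(m, s$parent, p$nseg - 1L))
        if (!sphere_clipped_empty(sp)) add(sp)
      }
      if (abs(r_par - r_child) > 1e-9) {
        # connection cone to the child's first-segment midpoint
        arcs <- s$arcs3
        Lc <- arcs[length(arcs)]
        mid_arc <- Lc / (2 * s$nseg)
        mid <- apply(pts, 2, function(col)
          stats::approx(arcs, col, xout = mid_arc, ties = "ordered")$y)
        add(csg_frustum(attach_pt, mid[1:3], r_par, mid[4] / 2,
                        segment_id(m, nm, 0L)))
      }
    }
  }
  structure(objs, class = "rxd_csg", segments = m$segments)
}

#' @export
print.rxd_csg <- function(x, ...) {
  tp <- vapply(x, `[[`, "", "type")
  cat("<rxd_csg> ", length(x), " objects (", sum(tp == "frustum"),
      " frusta, ", sum(tp == "sphere"), " spheres)\n", sep = "")
  invisible(x)
}
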