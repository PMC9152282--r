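#' Create a neurite section
#'
#' A section is an unbranched neurite described by an ordered list of
#' point-diameter samples `(x, y, z; d)`. Sections are assembled into a
#' tree-structured [morphology()]; every non-root section has exactly one
#' parent and attaches to it at an arc-length fraction `parent_x`.
#'
#' @param name unique section identifier.
#' @param points numeric matrix with columns `x, y, z, d` (micrometers);
#'   at least two rows.
#' @param nseg number of electrical compartments ("segments") the section is
#'   divided into; concentrations reported to membrane mechanisms live per
#'   segment.
#' @param parent name of the parent section, or `NULL` for the root.
#' @param parent_x arc-length fraction in `[0, 1]` of the parent at which this
#'   section attaches (1 = distal end; interior values are used for spines).
#' @param pt3d_style if `TRUE`, the first point is taken as given rather than
#'   being assumed to lie on the parent centroid; used together with
#'   [spine_attach_offset()] to start a spine neck almost a radius away from
#'   the dendrite centroid while keeping its perimeter inside the dendrite.
#' @return an object of class `rxd_section`.
#' @seealso [morphology()], [read_swc()]
#' @export
section <- function(name, points, nseg = 1L, parent = NULL, parent_x = 1,
                    pt3d_style = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 4L) stop("`points` must have columns x, y, z, d")
  colnames(points) <- c("x", "y", "z", "d")
  if (nrow(points) < 2L) stop("a section needs at least 2 points")
  if (!all(is.finite(points))) stop("section coordinates must be finite")
  if (any(points[, "d"] < 0)) stop("diameters must be non-negative")
  nseg <- as.integer(nseg)
  if (nseg < 1L) stop("nseg must be >= 1")
  # drop consecutive duplicate samples (zero-length frusta)
  keep <- c(TRUE, rowSums(abs(diff(points[, 1:3, drop = FALSE]))) > 0)
  points <- points[keep, , drop = FALSE]
  if (nrow(points) < 2L) stop("degenerate section: zero length")
  structure(list(name = name, points = points, nseg = nseg,
                 parent = parent, parent_x = parent_x,
                 pt3d_style = isTRUE(pt3d_style)),
            class = "rxd_section")
}

#' Assemble sections into a morphology tree
#'
#' @param ... `rxd_section` objects (or a single list of them).
#' @return an object of class `rxd_morphology` with fields `sections` (named
#'   list) and `root` (name of the unique root section).
#' @export
morphology <- function(...) {
  secs <- list(...)
  if (length(secs) == 1L && !inherits(secs[[1L]], "rxd_section")) secs <- secs[[1L]]
  names(secs) <- vapply(secs, `[[`, "", "name")
  if (anyDuplicated(names(secs))) stop("duplicate section names")
  roots <- names(secs)[vapply(secs, function(s) is.null(s$parent), TRUE)]
  if (length(secs) && length(roots) != 1L)
    stop("morphology must have exactly one root section (found ",
         length(roots), ")")
  for (s in secs) {
    if (!is.null(s$parent) && !s$parent %in% names(secs))
      stop("section '", s$name, "' refers to unknown parent '", s$parent, "'")
  }
  m <- structure(list(sections = secs,
                      root = if (length(secs)) roots else character()),
                 class = "rxd_morphology")
  assert_tree(m)
  m
}

assert_tree <- function(m) {
  if (!length(m$sections)) return(invisible(m))
  seen <- character()
  walk <- function(nm) {
    if (nm %in% seen) stop("cycle detected at section '", nm, "'")
    seen <<- c(seen, nm)
    kids <- names(m$sections)[vapply(m$sections, function(s)
      identical(s$parent, nm), TRUE)]
    for (k in kids) walk(k)
  }
  walk(m$root)
  if (length(seen) != length(m$sections))
    stop("morphology is not connected: unreachable sections ",
         paste(setdiff(names(m$sections), seen), collapse = ", "))
  invisible(m)
}

#' @export
print.rxd_morphology <- function(x, ...) {
  cat("<rxd_morphology> ", length(x$sections), " section(s)\n", sep = "")
  for (s in x$sections) {
    cat(sprintf("  %s: %d pts, L=%.3g um, nseg=%d%s\n", s$name,
                nrow(s$points), section_length(s), s$nseg,
                if (is.null(s$parent)) " (root)" else
                  sprintf(" <- %s@%.3g", s$parent, s$parent_x)))
  }
  invisible(x)
}

section_arcs <- function(sec) {
  p <- sec$points[, 1:3, drop = FALSE]
  c(0, cumsum(sqrt(rowSums(diff(p)^2))))
}

section_length <- function(sec) {
  a <- section_arcs(sec)
  a[length(a)]
}

#' Split sections into electrical compartments
#'
#' Inserts additional interpolated points at segment boundaries (arc-length
#' positions `k/nseg`) so that every frustum between consecutive points lies
#' wholly within one electrical compartment. Position and diameter are
#' interpolated linearly. Also tabulates per-segment arc intervals, 1D frusta
#' volumes and lateral areas, and the path distance of each segment center
#' from the root (used by the root-closest voxel ownership rule).
#'
#' @param m an `rxd_morphology`.
#' @param nseg_map optional named list/vector overriding `nseg` per section.
#' @return the morphology with augmented per-section points, a
#'   `frustum_seg` index per frustum, and a `segments` data.frame
#'   (`sec`, `seg`, `x0`, `x1`, `length`, `path_center`, `vol1d`, `area1d`).
#' @export
segmentize <- function(m, nseg_map = NULL) {
  stopifnot(inherits(m, "rxd_morphology"))
  if (!is.null(nseg_map)) {
    for (nm in names(nseg_map)) {
      if (!nm %in% names(m$sections)) stop("nseg_map: unknown section '", nm, "'")
      m$sections[[nm]]$nseg <- as.integer(nseg_map[[nm]])
    }
  }
  # path distance from root to each section's 0-end
  path0 <- stats::setNames(numeric(length(m$sections)), names(m$sections))
  order_top <- topo_order(m)
  for (nm in order_top) {
    s <- m$sections[[nm]]
    if (!is.null(s$parent)) {
      path0[nm] <- path0[s$parent] +
        section_length(m$sections[[s$parent]]) * s$parent_x
    }
  }
  segs <- list()
  gid <- 0L
  for (nm in order_top) {
    s <- m$sections[[nm]]
    if (s$nseg < 1L) stop("nseg must be >= 1 for section '", nm, "'")
    arcs <- section_arcs(s)
    L <- arcs[length(arcs)]
    if (L <= 0) stop("degenerate section '", nm, "': zero length")
    bnd <- L * seq_len(s$nseg - 1L) / s$nseg
    allarc <- sort(unique(c(arcs, bnd)))
    # drop near-duplicates from boundaries coinciding with existing points
    tol <- 1e-9 * L
    allarc <- allarc[c(TRUE, diff(allarc) > tol)]
    pts <- apply(s$points, 2, function(col) stats::approx(arcs, col, xout = allarc,
                                                          ties = "ordered")$y)
    pts <- matrix(pts, ncol = 4, dimnames = list(NULL, c("x", "y", "z", "d")))
    mid <- (allarc[-length(allarc)] + allarc[-1L]) / 2
    fseg <- pmin(s$nseg - 1L, floor(mid / L * s$nseg))
    m$sections[[nm]]$points3 <- pts
    m$sections[[nm]]$arcs3 <- allarc
    m$sections[[nm]]$frustum_seg <- as.integer(fseg)
    r <- pts[, "d"] / 2
    h <- diff(allarc)
    fvol <- pi / 3 * h * (r[-length(r)]^2 + r[-length(r)] * r[-1L] + r[-1L]^2)
    farea <- pi * (r[-length(r)] + r[-1L]) * sqrt(h^2 + diff(r)^2)
    for (k in seq_len(s$nseg) - 1L) {
      sel <- fseg == k
      segs[[length(segs) + 1L]] <- data.frame(
        sec = nm, seg = k, x0 = k / s$nseg, x1 = (k + 1) / s$nseg,
        length = L / s$nseg,
        path_center = path0[nm] + L * (k + 0.5) / s$nseg,
        vol1d = sum(fvol[sel]), area1d = sum(farea[sel]),
        stringsAsFactors = FALSE)
    }
  }
  m$segments <- do.call(rbind, segs)
  m$segments$id <- seq_len(nrow(m$segments))
  m$segmentized <- TRUE
  m
}

topo_order <- function(m) {
  out <- character()
  walk <- function(nm) {
    out <<- c(out, nm)
    kids <- names(m$sections)[vapply(m$sections, function(s)
      identical(s$parent, nm), TRUE)]
    for (k in kids) walk(k)
  }
  if (length(m$sections)) walk(m$root)
  out
}

segment_id <- function(m, sec, seg) {
  i <- which(m$segments$sec == sec & m$segments$seg == seg)
  if (!length(i)) stop("no such segment ", sec, "[", seg, "]")
  m$segments$id[i]
}

#' Warn about frusta too small for a voxel size
#'
#' Marching cubes requires every surface voxel to have corners on both sides
#' of the surface, which fails when a frustum's length or diameter is smaller
#' than the largest distance that fits within a voxel. Frusta with length or
#' diameter below `sqrt(3)*dx` (the voxel space diagonal) are reported, and a
#' conservative voxel size of one third of the smallest frustum dimension is
#' suggested.
#'
#' @param m morphology (segmentized or raw; segment boundaries add frusta and
#'   are included when present).
#' @param dx candidate voxel edge, micrometers.
#' @return list with `warnings` (data.frame: section, frustum, length,
#'   diameter) and `suggested_dx` (`min(length, diameter)/3` over all frusta;
#'   `NA` for an empty morphology).
#' @export
suggest_dx <- function(m, dx) {
  stopifnot(dx > 0)
  rows <- list(); mindim <- Inf
  for (s in m$sections) {
    pts <- if (!is.null(s$points3)) s$points3 else s$points
    arcs <- if (!is.null(s$arcs3)) s$arcs3 else section_arcs(s)
    len <- diff(arcs)
    dia <- pmin(pts[-nrow(pts), "d"], pts[-1L, "d"])
    mindim <- min(mindim, len, dia)
    bad <- which(len < sqrt(3) * dx | dia < sqrt(3) * dx)
    for (i in bad) {
      rows[[length(rows) + 1L]] <- data.frame(
        sec = s$name, frustum = i, length = len[i], diameter = dia[i])
    }
  }
  warnings <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sec = character(), frustum = integer(),
               length = numeric(), diameter = numeric())
  list(warnings = warnings,
       suggested_dx = if (is.finite(mindim)) mindim / 3 else NA_real_)
}

#' Maximum spine-neck displacement from the dendrite centroid
#'
#' When a spine neck of radius `r_n` attaches orthogonally to a cylindrical
#' dendrite of radius `r_d`, starting the neck at the dendrite centroid puts
#' most of it inside the dendrite. The neck start can be shifted up to
#' `d = r_d - sqrt(r_d^2 - r_n^2)` short of a full radius while keeping the
#' neck cross-section's perimeter inside the dendrite (right triangle with
#' hypotenuse `r_d`, legs `r_n` and `r_d - d`).
#'
#' @param r_d dendrite radius, micrometers.
#' @param r_n spine neck radius, micrometers; requires `0 <= r_n <= r_d`.
#' @return displacement `d` in micrometers.
#' @export
spine_attach_offset <- function(r_d, r_n) {
  if (any(r_n < 0) || any(r_n > r_d)) stop("need 0 <= r_n <= r_d")
  r_d - sqrt(r_d^2 - r_n^2)
}
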