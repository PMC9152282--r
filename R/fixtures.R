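#' Validation fixture geometries
#'
#' Programmatic generators for every geometry used in the validation studies,
#' so no external reconstruction is needed. All dimensions in micrometers.
#'
#' @name fixtures
NULL

orientation_axis <- function(phi, theta) {
  ax <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  # snap roundoff-level components so canonical orientations are exactly
  # grid-aligned (a 1e-16 tilt makes corners that lie exactly on the surface
  # flip inconsistently along a voxel column)
  ax[abs(ax) < 1e-12] <- 0
  ax / sqrt(sum(ax^2))
}

#' Draw reproducible uniformly random orientations on the sphere
#'
#' `phi` uniform on `[0, 2*pi)`, `cos(theta)` uniform on `[-1, 1]`.
#'
#' @param n number of orientations.
#' @param seed optional integer seed (local RNG state; the caller's RNG is
#'   untouched).
#' @return data.frame with columns `phi`, `theta`.
#' @export
random_orientations <- function(n, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  data.frame(phi = stats::runif(n, 0, 2 * pi),
             theta = acos(stats::runif(n, -1, 1)))
}

#' Cylinder fixture
#'
#' A two-point section of length `L` and diameter `d`, rotated about a fixed
#' anchor so the axis points along the `(phi, theta)` spherical direction.
#'
#' @param L,d length and diameter.
#' @param phi,theta orientation (defaults: axis along +x).
#' @param nseg electrical compartments.
#' @param anchor either "center" (rotate about the midpoint, which stays at
#'   the origin) or "start" (the 0-end stays at the origin).
#' @return an `rxd_morphology` with one section `cyl`.
#' @export
make_cylinder <- function(L = 5, d = 2, phi = 0, theta = pi / 2, nseg = 1L,
                          anchor = c("center", "start")) {
  stopifnot(L > 0, d > 0)
  anchor <- match.arg(anchor)
  ax <- orientation_axis(phi, theta)
  p0 <- if (anchor == "center") -L / 2 * ax else c(0, 0, 0)
  p1 <- p0 + L * ax
  morphology(section("cyl", rbind(c(p0, d), c(p1, d)), nseg = nseg))
}

#' Y-shaped branching fixture
#'
#' One section from the origin to `(arm_len, 0, 0)`, with two child sections
#' continuing at `+angle` and `-angle` in the xy-plane, all of diameter `d`.
#' With the defaults the children end at `(10 + 5*sqrt(3), +/-5, 0)`, i.e.
#' 30 degree changes in either direction.
#'
#' @param arm_len arm length (all three arms).
#' @param d diameter.
#' @param angle branching angle in radians (default 30 degrees).
#' @param nseg per-section electrical compartments.
#' @return an `rxd_morphology` with sections `trunk`, `br1`, `br2`.
#' @export
make_y <- function(arm_len = 10, d = 2, angle = pi / 6, nseg = 1L) {
  j <- c(arm_len, 0, 0)
  e1 <- j + arm_len * c(cos(angle), sin(angle), 0)
  e2 <- j + arm_len * c(cos(angle), -sin(angle), 0)
  morphology(
    section("trunk", rbind(c(0, 0, 0, d), c(j, d)), nseg = nseg),
    section("br1", rbind(c(j, d), c(e1, d)), nseg = nseg, parent = "trunk"),
    section("br2", rbind(c(j, d), c(e2, d)), nseg = nseg, parent = "trunk"))
}

#' Stepped-cylinder fixture (abrupt diameter change)
#'
#' Two collinear connected cylinders along the x-axis: length `L1`, diameter
#' `d1` with `n1` segments joined to length `L2`, diameter `d2` with `n2`
#' segments. The abrupt diameter change produces the CTNG connection cone
#' from the wide cylinder's rim to the midpoint of the narrow cylinder's
#' first segment.
#'
#' @param L1,d1,n1 first cylinder length, diameter, nseg.
#' @param L2,d2,n2 second cylinder length, diameter, nseg.
#' @return an `rxd_morphology` with sections `big`, `small`.
#' @export
make_stepped <- function(L1 = 5, d1 = 5, n1 = 9L, L2 = 5, d2 = 1, n2 = 5L) {
  morphology(
    section("big", rbind(c(0, 0, 0, d1), c(L1, 0, 0, d1)), nseg = n1),
    section("small", rbind(c(L1, 0, 0, d2), c(L1 + L2, 0, 0, d2)), nseg = n2,
            parent = "big"))
}

#' Spiny dendrite fixture
#'
#' A cylindrical dendrite along the x-axis with two spines (cylindrical neck
#' plus cylindrical head) attached orthogonally at arc position `attach_at`,
#' separated by `angle_sep` around the dendrite circumference and centered on
#' that separation. Each neck starts `spine_attach_offset(r_d, r_n)` short of
#' a dendrite radius from the centroid so its perimeter stays inside the
#' dendrite (`pt3d_style` attachment).
#'
#' @param d_dend,L_dend dendrite diameter and length.
#' @param neck_L,neck_d spine neck length and diameter.
#' @param head_L,head_d spine head length and diameter.
#' @param angle_sep angular separation of the two spines, radians
#'   (30 or 180 degrees in the validation study).
#' @param attach_at arc position of both spines along the dendrite.
#' @param nseg_dend dendrite nseg.
#' @return an `rxd_morphology` with sections `dend`, `neck1`, `head1`,
#'   `neck2`, `head2`.
#' @export
make_spiny <- function(d_dend = 2.5, L_dend = 6, neck_L = 3, neck_d = 0.1,
                       head_L = 0.5, head_d = 0.6, angle_sep = pi / 6,
                       attach_at = 3, nseg_dend = 1L) {
  stopifnot(neck_d <= d_dend)
  r_d <- d_dend / 2; r_n <- neck_d / 2
  start_r <- r_d - spine_attach_offset(r_d, r_n)
  secs <- list(section("dend", rbind(c(0, 0, 0, d_dend),
                                     c(L_dend, 0, 0, d_dend)),
                       nseg = nseg_dend))
  for (k in 1:2) {
    th <- (k - 1.5) * angle_sep  # symmetric about +y
    u <- c(0, cos(th), sin(th))
    base <- c(attach_at, 0, 0)
    n0 <- base + start_r * u
    n1 <- base + (start_r + neck_L) * u
    h1 <- base + (start_r + neck_L + head_L) * u
    secs[[length(secs) + 1L]] <-
      section(paste0("neck", k), rbind(c(n0, neck_d), c(n1, neck_d)),
              parent = "dend", parent_x = attach_at / L_dend,
              pt3d_style = TRUE)
    secs[[length(secs) + 1L]] <-
      section(paste0("head", k), rbind(c(n1, head_d), c(h1, head_d)),
              parent = paste0("neck", k))
  }
  morphology(secs)
}
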