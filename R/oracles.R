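#' Closed-form diffusion from an interval source on a line
#'
#' Concentration at position `x`, time `t` for 1D diffusion from an initial
#' concentration `C` on `[A, B]` (0 elsewhere), obtained by integrating the
#' 1D heat kernel `G(x,t) = (4 pi D t)^{-1/2} exp(-x^2 / 4Dt)` over the
#' source interval and evaluating via the error function. For a finite
#' domain `[0, L]` with reflective ends, image sources are added (method of
#' images) until the next term changes the result by less than 1e-15.
#'
#' @param x position(s), um.
#' @param t time, ms (> 0).
#' @param d diffusion constant, um^2/ms.
#' @param a,b source interval, um.
#' @param c0 initial source concentration, mM.
#' @param domain optional length-2 vector `c(0, L)` for a reflective finite
#'   domain.
#' @return concentration(s), mM.
#' @export
green1d <- function(x, t, d, a, b, c0 = 1, domain = NULL) {
  if (any(t <= 0)) stop("t must be > 0")
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  s <- 2 * sqrt(d * t)
  plug <- function(aa, bb) c0 / 2 * (erf((x - aa) / s) - erf((x - bb) / s))
  out <- plug(a, b)
  if (!is.null(domain)) {
    L <- domain[2] - domain[1]
    for (k in seq_len(1000L)) {
      # reflections across both ends at offsets 2kL, interval mirrored
      add <- plug(2 * k * L + a, 2 * k * L + b) +
        plug(-2 * k * L + a, -2 * k * L + b) +
        plug(2 * domain[1] - b - 2 * (k - 1) * L,
             2 * domain[1] - a - 2 * (k - 1) * L) +
        plug(2 * domain[2] - b + 2 * (k - 1) * L,
             2 * domain[2] - a + 2 * (k - 1) * L)
      out <- out + add
      if (max(abs(add)) < 1e-15) break
    }
  }
  out
}

#' Closed-form diffusion from a box source in 3D space
#'
#' Separable product of three 1D interval solutions for an axis-aligned box
#' of initial concentration `c0` (the 3D heat kernel
#' `G = (4 pi D t)^{-3/2} exp(-|x|^2/4Dt)` integrated over the box).
#'
#' @param p evaluation point(s): length-3 vector or n x 3 matrix, um.
#' @param t time, ms (> 0).
#' @param d diffusion constant, um^2/ms.
#' @param box 2 x 3 matrix: rows are the lower and upper corners, um.
#' @param c0 initial concentration in the box, mM.
#' @return concentration(s), mM.
#' @export
green3d_box <- function(p, t, d, box = rbind(c(-2, -2, -2), c(2, 2, 2)),
                        c0 = 1) {
  if (any(t <= 0)) stop("t must be > 0")
  p <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  out <- rep(c0, nrow(p))
  for (ax in 1:3) {
    out <- out * green1d(p[, ax], t, d, box[1, ax], box[2, ax], c0 = 1)
  }
  out
}

#' Analytic plane-wave speed of the scalar bistable equation
#'
#' For `u_t = D u_xx - u (1 - u)(alpha - u)` the traveling front moves at
#' `c = sqrt(2) (1/2 - alpha)` when `D = 1`; speed scales with `sqrt(D)`.
#'
#' @param alpha threshold concentration (< 1/2 for a rightward wave).
#' @param d diffusion constant, um^2/ms.
#' @return wave speed, um/ms.
#' @export
bistable_wave_speed <- function(alpha, d = 1) {
  sqrt(2) * (0.5 - alpha) * sqrt(d)
}

#' Estimate wave speed from a recorded front trajectory
#'
#' The wave front at a sample time is the farthest position whose average 1D
#' concentration exceeds the threshold (interior dips behind the front are
#' ignored by construction). The speed is the distance between `x_start` and
#' `x_end` divided by the difference of the threshold-crossing times, each
#' linearly interpolated between samples.
#'
#' @param times sample times, ms.
#' @param conc matrix of mean 1D concentration, `length(times)` rows by
#'   `length(positions)` columns (optional when `front` is given).
#' @param positions positions (um) for the columns of `conc`.
#' @param front precomputed front positions per sample (overrides `conc`).
#' @param threshold front-defining concentration (default 0.5).
#' @param x_start,x_end positions whose crossing times define the speed.
#' @return list with `speed` (um/ms), `t_start`, `t_end`.
#' @export
track_wave_front <- function(times, conc = NULL, positions = NULL,
                             front = NULL, threshold = 0.5,
                             x_start = 100, x_end = 200) {
  if (is.null(front)) {
    stopifnot(!is.null(conc), !is.null(positions))
    front <- apply(conc, 1L, function(row) {
      w <- which(row > threshold)
      if (!length(w)) -Inf else max(positions[w])
    })
  }
  crossing <- function(xstar) {
    above <- front >= xstar
    if (!any(above)) stop("front never reaches x = ", xstar)
    k <- which(above)[1L]
    if (k == 1L) return(times[1L])
    f0 <- front[k - 1L]; f1 <- front[k]
    if (!is.finite(f0) || f1 == f0) return(times[k])
    times[k - 1L] + (xstar - f0) / (f1 - f0) * (times[k] - times[k - 1L])
  }
  t1 <- crossing(x_start); t2 <- crossing(x_end)
  list(speed = (x_end - x_start) / (t2 - t1), t_start = t1, t_end = t2)
}
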