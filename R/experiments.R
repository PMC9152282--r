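#' Cylinder discretization convergence study
#'
#' Voxelizes a cylinder of diameter `d` and length `L` (analytic volume
#' `pi L d^2/4`, lateral+cap area `pi d L + pi d^2/2`) at each `dx` over
#' random orientations and reports volume and surface-area errors.
#'
#' @param n_orient number of random orientations.
#' @param dx_values voxel edges to test, um.
#' @param L,d cylinder length and diameter, um.
#' @param vr partial-volume resolution (the convergence study uses 1, i.e.
#'   no sub-voxel refinement).
#' @param seed RNG seed for the orientations.
#' @param area whether to also compute marching-cubes areas.
#' @return data.frame with one row per (dx, orientation): `dx`, `phi`,
#'   `theta`, `vol`, `vol_err`, and (if requested) `area`, `area_err`.
#' @export
cylinder_study <- function(n_orient = 100L,
                           dx_values = 2^-seq(1, 4, by = 0.5),
                           L = 5, d = 2, vr = 1L, seed = 1L, area = TRUE) {
  ori <- random_orientations(n_orient, seed = seed)
  vol_true <- pi * L * d^2 / 4
  area_true <- pi * d * L + pi * d^2 / 2
  rows <- list()
  for (dx in dx_values) {
    for (i in seq_len(n_orient)) {
      m <- make_cylinder(L = L, d = d, phi = ori$phi[i], theta = ori$theta[i])
      g <- voxelize(m, dx, vr = vr, sr = 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        dx = dx, phi = ori$phi[i], theta = ori$theta[i],
        vol = g$totals$volume, vol_err = g$totals$volume - vol_true,
        area = if (area) g$totals$area else NA_real_,
        area_err = if (area) g$totals$area - area_true else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Log-log convergence slope of mean absolute error vs dx
#' @param df output of [cylinder_study()].
#' @param what `"vol_err"` or `"area_err"`.
#' @return fitted slope.
#' @export
convergence_slope <- function(df, what = "vol_err") {
  agg <- tapply(abs(df[[what]]), df$dx, mean)
  unname(stats::coef(stats::lm(log(agg) ~ log(as.numeric(names(agg)))))[2])
}

#' Axial line-diffusion validation on a grid-aligned cylinder
#'
#' Diffusion of an initial 1 mM plug on `[x0, x1]` um along a cylinder of
#' length `L` and diameter `d` lying on the x axis, compared per x column
#' (volume-weighted) against the closed-form interval solution.
#'
#' @param dx voxel edge, um.
#' @param t_end end time, ms.
#' @param dt step, ms.
#' @param L,d cylinder dimensions, um.
#' @param x0,x1 initial plug, um.
#' @param D diffusion constant.
#' @return list with `max_abs_err` (mM), `profile` data.frame
#'   (`x`, `conc`, `exact`).
#' @export
line_diffusion_experiment <- function(dx = 0.5, t_end = 100, dt = 0.025,
                                      L = 200, d = 1, x0 = 95, x1 = 105,
                                      D = 1) {
  m <- make_cylinder(L = L, d = d, anchor = "start")
  g <- voxelize(m, dx)
  xc <- voxel_centers(g)[, 1]
  u <- as.numeric(xc > x0 & xc < x1)
  lines <- build_lines(g)
  u <- dg_adi_step(u, g, lines, D, dt, nsteps = round(t_end / dt))
  num <- tapply(u * g$vol, xc, sum)
  den <- tapply(g$vol, xc, sum)
  x <- as.numeric(names(num))
  exact <- green1d(x, t_end, D, x0, x1, domain = c(0, L))
  prof <- data.frame(x = x, conc = as.numeric(num / den), exact = exact)
  list(max_abs_err = max(abs(prof$conc - prof$exact)), profile = prof)
}

#' 3D point-source (box) diffusion validation
#'
#' Initial 1 mM in the cube `[-w/2, w/2]^3` inside a reflective cylinder
#' (diameter `domain_d`, height `domain_h`, axis along z) large enough that
#' the boundary is negligible at `t_end`; simulated concentrations at the
#' voxels containing `n_pts` random points within `r_eval` of the origin are
#' compared to the separable box Green's-function solution at the voxel
#' centers.
#'
#' @param dx voxel edge, um.
#' @param t_end end time, ms.
#' @param dt step, ms.
#' @param domain_d,domain_h domain cylinder diameter and height, um.
#' @param w source cube edge, um.
#' @param r_eval evaluation radius, um.
#' @param n_pts number of random evaluation points.
#' @param D diffusion constant.
#' @param seed RNG seed for the points.
#' @return list with `max_rel_err_pct`, `pts` data.frame.
#' @export
point_source_experiment <- function(dx = 0.25, t_end = 20, dt = 0.025,
                                    domain_d = 32, domain_h = 32, w = 4,
                                    r_eval = 4, n_pts = 100L, D = 1,
                                    seed = 1L) {
  m <- make_cylinder(L = domain_h, d = domain_d, theta = 0)  # axis along z
  g <- voxelize(m, dx)
  ctr <- voxel_centers(g)
  u <- as.numeric(ctr[, 1] > -w / 2 & ctr[, 1] < w / 2 &
                  ctr[, 2] > -w / 2 & ctr[, 2] < w / 2 &
                  ctr[, 3] > -w / 2 & ctr[, 3] < w / 2)
  lines <- build_lines(g)
  u <- dg_adi_step(u, g, lines, D, dt, nsteps = round(t_end / dt))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  # uniform in the ball of radius r_eval
  az <- stats::runif(n_pts, 0, 2 * pi)
  cz <- stats::runif(n_pts, -1, 1)
  rr <- r_eval * stats::runif(n_pts)^(1 / 3)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  pts <- cbind(rr * sqrt(1 - cz^2) * cos(az), rr * sqrt(1 - cz^2) * sin(az),
               rr * cz)
  vox <- voxel_at(g, pts)
  ok <- !is.na(vox)
  vox <- vox[ok]; pts <- pts[ok, , drop = FALSE]
  exact <- green3d_box(ctr[vox, , drop = FALSE], t_end, D,
                       box = rbind(rep(-w / 2, 3), rep(w / 2, 3)))
  rel <- abs(u[vox] - exact) / exact
  list(max_rel_err_pct = 100 * max(rel),
       pts = data.frame(r = sqrt(rowSums(pts^2)), sim = u[vox],
                        exact = exact, rel_err = rel))
}

#' Hybrid 1D-3D diffusion error study on the 153 um cylinder
#'
#' Length-153, diameter-2 cylinder split into three 51-um sections with a 1D
#' discretization of two segments per micron; 1 mM initial plug on
#' `[70, 83]` um; runs one of four discretization strategies and reports the
#' maximum absolute error of the volume-weighted concentration per position
#' against the closed-form solution at `t = 50` ms.
#'
#' @param mode `"3d_outer"` (1D middle third), `"3d_middle"`, `"pure3d"`,
#'   or `"pure1d"`.
#' @param dx voxel edge, um.
#' @param vr partial-volume resolution.
#' @param t_end,dt time parameters, ms.
#' @param D diffusion constant.
#' @return list with `max_abs_err` (mM), `profile`, `mass_drift` (relative).
#' @export
hybrid_error_experiment <- function(mode = c("3d_outer", "3d_middle",
                                             "pure3d", "pure1d"),
                                    dx = 0.25, vr = 2L, t_end = 50,
                                    dt = 0.025, D = 1) {
  mode <- match.arg(mode)
  L <- 153; nseg_per_um <- 2L
  m <- morphology(
    section("s1", rbind(c(0, 0, 0, 2), c(51, 0, 0, 2)), nseg = 102L),
    section("s2", rbind(c(51, 0, 0, 2), c(102, 0, 0, 2)), nseg = 102L,
            parent = "s1"),
    section("s3", rbind(c(102, 0, 0, 2), c(153, 0, 0, 2)), nseg = 102L,
            parent = "s2"))
  init <- function(sec, xfrac) {
    x0 <- c(s1 = 0, s2 = 51, s3 = 102)[sec]
    x <- x0 + 51 * xfrac
    as.numeric(x > 70 & x < 83)
  }
  exact_at <- function(x) green1d(x, t_end, D, 70, 83, domain = c(0, L))
  nsteps <- round(t_end / dt)
  if (mode == "pure1d") {
    m <- segmentize(m)
    cab <- cable_state(m, d = D, initial = init)
    m0 <- sum(cab$u * cab$vol)
    cab <- step_1d_diffusion(cab, dt, nsteps = nsteps)
    x <- 51 * (cab$segs$x0 + cab$segs$x1) / 2 +
      c(s1 = 0, s2 = 51, s3 = 102)[cab$segs$sec]
    prof <- data.frame(x = x, conc = cab$u, exact = exact_at(x))
    drift <- abs(sum(cab$u * cab$vol) - m0) / m0
  } else {
    map <- switch(mode,
      "3d_outer" = set_solve_type(m, c("s1", "s3"), 3L,
                                  map = set_solve_type(m, "s2", 1L)),
      "3d_middle" = set_solve_type(m, "s2", 3L,
                                   map = set_solve_type(m, c("s1", "s3"), 1L)),
      "pure3d" = set_solve_type(m, dimension = 3L))
    hm <- hybrid_model(m, map, dx = dx, d = D, initial = init, dt = dt,
                       vr = vr)
    m0 <- hybrid_mass(hm)
    hm <- hybrid_step(hm, nsteps = nsteps)
    prof <- hybrid_profile(hm)
    prof$exact <- exact_at(prof$x)
    drift <- abs(hybrid_mass(hm) - m0) / m0
  }
  list(max_abs_err = max(abs(prof$conc - prof$exact)), profile = prof,
       mass_drift = drift)
}

#' Bistable traveling-wave orientation study
#'
#' Simulates `u_t = D Lap u - u(1-u)(alpha-u)` on randomly oriented
#' cylinders (length 251 um, diameter 2 um), initialized to 1 on the first
#' 50 um, and estimates the wave speed from the time the front (farthest
#' segment with mean 1D concentration over 0.5) takes to move between 100
#' and 200 um of arc length; relative errors are against the analytic plane
#' wave speed.
#'
#' @param n_orient number of random orientations.
#' @param dx voxel edge, um.
#' @param alpha bistable threshold.
#' @param D diffusion constant.
#' @param dt step, ms.
#' @param L,d cylinder dimensions; `nseg` 1D compartments (2 per um).
#' @param seed RNG seed.
#' @return data.frame per orientation: `phi`, `theta`, `speed`, `rel_err`.
#' @export
wave_speed_study <- function(n_orient = 5L, dx = 0.25, alpha = 0.25, D = 1,
                             dt = 0.025, L = 251, d = 2, nseg = 502L,
                             seed = 1L) {
  ori <- random_orientations(n_orient, seed = seed)
  c_true <- bistable_wave_speed(alpha, D)
  rows <- list()
  for (i in seq_len(n_orient)) {
    m <- make_cylinder(L = L, d = d, phi = ori$phi[i], theta = ori$theta[i],
                       nseg = nseg, anchor = "start")
    g <- voxelize(m, dx)
    lines <- build_lines(g)
    segrow <- match(g$seg, g$segments$id)
    segpos <- g$segments$path_center  # arc position of segment center
    u <- as.numeric(segpos[segrow] < 50)
    # advance in chunks (0-based segment index per voxel drives the front
    # tracker) until the front has cleared the measurement window
    nsteps_max <- ceiling((L - 50) / c_true / dt * 2)
    chunk <- 2000L
    fronts <- numeric(); done <- 0L
    while (done < nsteps_max) {
      res <- cpp_advance(u, g$vol, g$frac,
                         lines$x$idx, lines$x$ptr, lines$y$idx, lines$y$ptr,
                         lines$z$idx, lines$z$ptr,
                         D, g$dx, dt, chunk,
                         1L, alpha, integer(), numeric(), 0L,
                         as.integer(segrow - 1L), nrow(g$segments),
                         segpos, 0.5, TRUE,
                         integer(), FALSE, integer())
      u <- res$u
      fronts <- c(fronts, res$front)
      done <- done + chunk
      if (max(res$front) >= 202) break
    }
    tw <- track_wave_front(times = dt * seq_along(fronts), front = fronts)
    rows[[i]] <- data.frame(phi = ori$phi[i], theta = ori$theta[i],
                            speed = tw$speed,
                            rel_err = abs(tw$speed - c_true) / c_true)
  }
  do.call(rbind, rows)
}

#' Long-run conservation-of-mass check on the Y geometry
#'
#' Pure diffusion (D = 1) on the Y fixture from 1 uM on the trunk and 100 nM
#' on the branches; tracks the relative change of total mass over `nsteps`
#' fixed steps of size `dt`.
#'
#' @param dt step, ms.
#' @param nsteps number of steps.
#' @param dx voxel edge.
#' @param mass_every record mass every this many steps.
#' @return list with `max_rel_drift` and the `mass` series.
#' @export
conservation_experiment <- function(dt = 0.025, nsteps = 1e5L, dx = 0.25,
                                    mass_every = 100L) {
  m <- make_y()
  g <- voxelize(m, dx)
  lines <- build_lines(g)
  secs <- g$segments$sec[match(g$seg, g$segments$id)]
  u <- ifelse(secs == "trunk", 1e-3, 1e-4)  # 1 uM / 100 nM in mM
  res <- cpp_advance(u, g$vol, g$frac,
                     lines$x$idx, lines$x$ptr, lines$y$idx, lines$y$ptr,
                     lines$z$idx, lines$z$ptr,
                     1, g$dx, dt, as.integer(nsteps),
                     0L, 0, integer(), numeric(), as.integer(mass_every),
                     integer(), 0L, numeric(), 0.5, FALSE,
                     integer(), FALSE, integer())
  m0 <- res$mass[1L]
  list(max_rel_drift = max(abs(res$mass - m0)) / m0, mass = res$mass)
}

#' Two-spine diffusion study
#'
#' Spines initially at 2 mM (neck + head voxels), dendrite at 0; substance
#' diffuses at 0.01 um^2/ms. Reports the peak concentration over dendrite
#' voxels and the time of the peak for a given angular separation.
#'
#' @param angle_sep separation of the two spines, radians.
#' @param dx voxel edge (0.05 um so the 0.1-um neck spans two voxels).
#' @param dt step, ms.
#' @param t_end simulated time, ms (peaks occur within 0.5 ms).
#' @param D diffusion constant.
#' @return list with `peak` (mM), `t_peak` (ms), `maxvals` series.
#' @export
spine_experiment <- function(angle_sep = pi / 6, dx = 0.05, dt = 0.025,
                             t_end = 1, D = 0.01) {
  m <- make_spiny(angle_sep = angle_sep)
  g <- voxelize(m, dx)
  secs <- g$segments$sec[match(g$seg, g$segments$id)]
  u <- ifelse(secs == "dend", 0, 2)
  dend <- which(secs == "dend")
  lines <- build_lines(g)
  nsteps <- round(t_end / dt)
  res <- cpp_advance(u, g$vol, g$frac,
                     lines$x$idx, lines$x$ptr, lines$y$idx, lines$y$ptr,
                     lines$z$idx, lines$z$ptr,
                     D, g$dx, dt, as.integer(nsteps),
                     0L, 0, integer(), numeric(), 0L,
                     integer(), 0L, numeric(), 0.5, FALSE,
                     integer(), TRUE, as.integer(dend - 1L))
  k <- which.max(res$maxvals)
  list(peak = res$maxvals[k], t_peak = k * dt, maxvals = res$maxvals)
}

#' Hodgkin-Huxley soma with 3D sodium accumulation
#'
#' Cylindrical soma (10 um long, 10 um diameter) with Hodgkin-Huxley
#' channels under continuous current injection; sodium enters through the
#' surface voxels (distributed by area), diffuses in 3D, and the surface
#' concentration feeds back on the sodium Nernst potential each step. A
#' matched well-mixed 1D run uses the same channel model.
#'
#' @param D_na sodium diffusion constant, um^2/ms.
#' @param dx voxel edge.
#' @param t_end simulated time, ms.
#' @param dt step, ms.
#' @param i_inject injected current, nA.
#' @param mode feedback voxels: `"surface"` or `"all"`.
#' @param oned if TRUE run the well-mixed 1D model instead.
#' @return list with `na_surface` (trace, mM), `v` (trace), `t` times.
#' @export
hh_soma_experiment <- function(D_na = 1e-4, dx = 0.5, t_end = 100,
                               dt = 0.025, i_inject = 0.1,
                               mode = "surface", oned = FALSE) {
  L <- 10; d <- 10
  m <- make_cylinder(L = L, d = d, anchor = "start")
  m <- segmentize(m)
  area1d <- m$segments$area1d[1L]  # summed frusta lateral area
  vol1d <- m$segments$vol1d[1L]
  hh <- hh_state(area = area1d)
  nsteps <- round(t_end / dt)
  tvec <- dt * seq_len(nsteps)
  if (oned) {
    nav <- numeric(nsteps); vv <- numeric(nsteps)
    for (s in seq_len(nsteps)) {
      adv <- hh_advance(hh, i_inject, dt)
      hh <- adv$state
      dna <- -adv$ina_nA * 1e-12 / rxd_constants()$FARADAY * 1e18 / vol1d
      hh$nai <- hh$nai + dna * dt
      nav[s] <- hh$nai; vv[s] <- hh$v
    }
    return(list(t = tvec, na_surface = nav, v = vv))
  }
  g <- voxelize(m, dx)
  lines <- build_lines(g)
  u <- rep(hh$nai, nrow(g$keys))
  segid <- g$segments$id[1L]
  nav <- numeric(nsteps); vv <- numeric(nsteps)
  for (s in seq_len(nsteps)) {
    adv <- hh_advance(hh, i_inject, dt)
    hh <- adv$state
    dist <- distribute_segment_current(adv$ina_nA, g, segid, z = 1)
    u[dist$voxels] <- u[dist$voxels] + dist$rate * dt
    u <- dg_adi_step(u, g, lines, D_na, dt)
    fb <- segment_feedback(g, u, mode = mode)
    hh$nai <- unname(fb[as.character(segid)])
    nav[s] <- hh$nai; vv[s] <- hh$v
  }
  list(t = tvec, na_surface = nav, v = vv)
}
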