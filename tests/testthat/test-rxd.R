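# dense diffusion operator A over an arbitrary stored voxel set, built
# independently of the line decomposition (the oracle for DG-ADI)
dense_operator <- function(grid, d) {
  n <- nrow(grid$keys)
  A <- matrix(0, n, n)
  for (ax in 1:3) {
    off <- c(0, 0, 0); off[ax] <- 1
    nb <- rxd3d:::enc_key(grid$keys[, 1] + off[1], grid$keys[, 2] + off[2],
                          grid$keys[, 3] + off[3])
    j <- match(nb, grid$enc)
    for (i in which(!is.na(j))) {
      gcond <- d * grid$dx * (grid$frac[i] + grid$frac[j[i]]) / 2
      A[i, j[i]] <- A[i, j[i]] + gcond / grid$vol[i]
      A[i, i] <- A[i, i] - gcond / grid$vol[i]
      A[j[i], i] <- A[j[i], i] + gcond / grid$vol[j[i]]
      A[j[i], j[i]] <- A[j[i], j[i]] - gcond / grid$vol[j[i]]
    }
  }
  A
}

test_that("line decomposition partitions the voxel set per axis", {
  g <- voxelize(make_cylinder(L = 2, d = 2), 0.5)
  l <- build_lines(g)
  n <- nrow(g$keys)
  for (ax in c("x", "y", "z")) {
    expect_equal(length(l[[ax]]$idx), n)
    expect_equal(sort(l[[ax]]$idx), 0:(n - 1L))
    expect_equal(l[[ax]]$ptr[length(l[[ax]]$ptr)], n)
  }
  # Y fixture: same partition property on a branched domain
  gy <- voxelize(make_y(), 0.5)
  ly <- build_lines(gy)
  for (ax in c("x", "y", "z"))
    expect_equal(length(ly[[ax]]$idx), nrow(gy$keys))
})

test_that("line runs match a brute-force run-length enumeration", {
  # L-shaped voxel set {(0..2,0,0)} + {(2,1..2,0)}
  keys <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0), c(2, 2, 0))
  g <- structure(list(keys = keys,
                      enc = sort(rxd3d:::enc_key(keys[, 1], keys[, 2],
                                                 keys[, 3]))),
                 class = "rxd_grid")
  l <- build_lines(g)
  lens_x <- sort(diff(l$x$ptr))
  lens_y <- sort(diff(l$y$ptr))
  expect_equal(lens_x, c(1L, 1L, 3L))
  expect_equal(lens_y, c(1L, 1L, 3L))
  expect_equal(sort(diff(l$z$ptr)), rep(1L, 5L))
})

test_that("uniform concentration is a diffusion fixed point", {
  g <- voxelize(make_y(), 0.5)
  l <- build_lines(g)
  u <- rep(3.7, nrow(g$keys))
  u2 <- dg_adi_step(u, g, l, 2, 0.025, 20L)
  expect_lt(max(abs(u2 - 3.7)), 1e-12)
})

test_that("DG-ADI matches a dense implicit oracle to splitting order", {
  g <- voxelize(make_cylinder(L = 1.5, d = 1.5), 0.5)  # < 100 voxels
  expect_lt(nrow(g$keys), 100L)
  l <- build_lines(g)
  A <- dense_operator(g, d = 1)
  set.seed(2)
  u0 <- runif(nrow(g$keys))
  n <- nrow(A)
  err_cn <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    dg <- dg_adi_step(u0, g, l, 1, dt)
    cn <- solve(diag(n) - dt / 2 * A, (diag(n) + dt / 2 * A) %*% u0)
    max(abs(dg - cn))
  }, 0)
  # splitting error O(dt^3) per step: halving dt shrinks the gap ~8x
  expect_gt(err_cn[1] / err_cn[2], 5)
  expect_gt(err_cn[2] / err_cn[3], 5)
  # and both stay consistent with dense backward Euler at O(dt^2)
  dt <- 0.025
  be <- solve(diag(n) - dt * A, u0)
  expect_lt(max(abs(dg_adi_step(u0, g, l, 1, dt) - be)), 10 * dt^2 * max(abs(A %*% u0)))
})

test_that("diffusion obeys the maximum principle and conserves mass", {
  g <- voxelize(make_y(), 0.25)
  l <- build_lines(g)
  set.seed(3)
  u <- runif(nrow(g$keys))
  m0 <- total_mass(u, g)
  u2 <- dg_adi_step(u, g, l, 1, 0.025, 50L)
  expect_lt(max(u2), max(u) + 1e-9)
  expect_gt(min(u2), min(u) - 1e-9)
  expect_equal(total_mass(u2, g), m0, tolerance = 1e-12)
})

test_that("implicit reaction step reproduces backward Euler decay", {
  g <- voxelize(make_cylinder(L = 1, d = 1), 0.5)
  mod <- rxd_model(g, species = list(species("u", d = 0, initial = 1)),
                   reactions = list(reaction(function(s) s$u,
                                             c(u = -1))),
                   dt = 0.025)
  mod <- reaction_step(mod)
  expect_equal(unique(round(mod$conc$u, 12)), round(1 / 1.025, 12))
})

test_that("bistable rate vanishes at its fixed points", {
  for (u0 in c(0, 0.25, 1)) {
    g <- voxelize(make_cylinder(L = 1, d = 1), 0.5)
    mod <- rxd_model(g, species = list(species("u", d = 0, initial = u0)),
                     reactions = list(reaction(
                       function(s) -s$u * (1 - s$u) * (0.25 - s$u),
                       c(u = 1))), dt = 0.1)
    mod <- reaction_step(mod)
    expect_equal(max(abs(mod$conc$u - u0)), 0, tolerance = 1e-10)
  }
})

test_that("no reactions and no fluxes leaves concentrations untouched", {
  g <- voxelize(make_cylinder(L = 1, d = 1), 0.5)
  mod <- rxd_model(g, species = list(species("u", d = 0, initial = 0.5)))
  expect_identical(reaction_step(mod)$conc$u, mod$conc$u)
})

test_that("parameters never change; states react but do not diffuse", {
  g <- voxelize(make_cylinder(L = 2, d = 1), 0.25)
  ctr <- voxel_centers(g)
  mod <- rxd_model(g, species = list(
    species("p", d = 1, initial = function(x, y, z) x, kind = "parameter"),
    species("s", d = 5, initial = function(x, y, z) as.numeric(x > 1),
            kind = "state")),
    reactions = list(reaction(function(st) st$p * 0.1, c(s = 1))),
    dt = 0.025)
  p0 <- mod$conc$p; s0 <- mod$conc$s
  mod <- sim_advance(mod, 4L)
  expect_identical(mod$conc$p, p0)
  # state changed by reaction only: increments proportional to p, and the
  # sharp step in s has not been smoothed by diffusion
  expect_equal(mod$conc$s - s0, mod$conc$p * 0.1 * 0.025 * 4,
               tolerance = 1e-9)
})

test_that("point fluxes inject the same mass regardless of dx and dt", {
  total <- function(dx, dt, nsteps) {
    g <- voxelize(make_cylinder(L = 2, d = 2), dx)
    v <- which(g$surface & g$area > 0)[1L]
    mod <- rxd_model(g, species = list(species("u", d = 1, initial = 0)),
                     fluxes = list(point_flux("u", v, g = 602214.076)),
                     dt = dt)
    mod <- sim_advance(mod, nsteps)
    total_mass(mod$conc$u, g, units = "molecules")
  }
  m1 <- total(0.5, 0.025, 40L)   # 1 ms at 602214.076 molecules/ms
  m2 <- total(0.25, 0.025, 40L)
  m3 <- total(0.5, 0.0125, 80L)
  expect_equal(m1, 602214.076, tolerance = 1e-9)
  expect_equal(m2, m1, tolerance = 1e-9)
  expect_equal(m3, m1, tolerance = 1e-9)
})

test_that("segment currents distribute by surface area", {
  g <- voxelize(make_cylinder(L = 5, d = 2, nseg = 1L), 0.25)
  segid <- g$segments$id[1L]
  dist <- distribute_segment_current(-0.1, g, segid, z = 1)  # inward 0.1 nA
  expect_equal(length(dist$voxels), sum(g$area > 0))
  # shares proportional to area
  share <- dist$rate * g$vol[dist$voxels]
  expect_equal(share / sum(share),
               g$area[dist$voxels] / sum(g$area[dist$voxels]),
               tolerance = 1e-12)
  # total mass rate: I/(zF) = 0.1e-9 / 96485 mol/s ~ 1.0364e-15
  mol_per_s <- sum(dist$rate * g$vol[dist$voxels]) * 1e-18 * 1000
  expect_equal(mol_per_s, 0.1e-9 / 96485, tolerance = 1e-6)
  expect_error(distribute_segment_current(1, g, 9999L, z = 1),
               "no surface voxels")
})

test_that("segment feedback is the volume-weighted surface mean", {
  g <- voxelize(make_stepped(), 0.25)
  u <- rep(2.5, nrow(g$keys))
  fb <- segment_feedback(g, u)
  expect_true(all(abs(fb - 2.5) < 1e-12))
  # hand-computed two-voxel weighted mean
  sel <- which(g$surface)[1:2]
  uu <- numeric(nrow(g$keys))
  uu[sel] <- c(0, 4)
  w <- g$vol[sel]
  seg <- g$seg[sel[1]]
  manual <- sum(uu[g$seg == seg & g$surface & g$area > 0] *
                g$vol[g$seg == seg & g$surface & g$area > 0]) /
    sum(g$vol[g$seg == seg & g$surface & g$area > 0])
  expect_equal(unname(segment_feedback(g, uu)[as.character(seg)]), manual)
  # mode = "all" averages over every voxel of the segment
  fb_all <- segment_feedback(g, uu, mode = "all")
  manual_all <- sum(uu[g$seg == seg] * g$vol[g$seg == seg]) /
    sum(g$vol[g$seg == seg])
  expect_equal(unname(fb_all[as.character(seg)]), manual_all)
})

test_that("total mass converts mM um^3 to mol and molecules", {
  g <- voxelize(make_cylinder(L = 2, d = 2), 0.5)
  u <- numeric(nrow(g$keys))
  i <- which(!g$surface)[1L]  # a full 1 um^3... (0.5^3) voxel
  u[i] <- 1 / g$vol[i]        # 1 mM um^3 total
  expect_equal(total_mass(u, g, "mol"), 1e-18, tolerance = 1e-12)
  expect_equal(total_mass(u, g, "molecules"), 602214.076, tolerance = 1e-9)
  expect_equal(total_mass(numeric(nrow(g$keys)), g), 0)
})
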