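straight_3sec <- function(nseg = 10L, L = 30, d = 2) {
  third <- L / 3
  morphology(
    section("s1", rbind(c(0, 0, 0, d), c(third, 0, 0, d)), nseg = nseg),
    section("s2", rbind(c(third, 0, 0, d), c(2 * third, 0, 0, d)),
            nseg = nseg, parent = "s1"),
    section("s3", rbind(c(2 * third, 0, 0, d), c(L, 0, 0, d)),
            nseg = nseg, parent = "s2"))
}

test_that("solve-type map is per section with last assignment winning", {
  m <- straight_3sec()
  map <- set_solve_type(m, dimension = 1L)
  map <- set_solve_type(m, c("s2", "s3"), 3L, map = map)
  map <- set_solve_type(m, "s3", 1L, map = map)
  expect_equal(unname(map[c("s1", "s2", "s3")]), c(1L, 3L, 1L))
  expect_error(set_solve_type(m, "nope", 3L), "unknown")
  expect_error(set_solve_type(m, "s1", 2L), "dimension")
})

test_that("an all-3D model has no junctions", {
  m <- segmentize(straight_3sec())
  map <- set_solve_type(m, dimension = 3L)
  hm <- hybrid_model(m, map, dx = 0.5)
  expect_null(hm$cable)
  expect_true(all(lengths(hm$junctions) == 0L))
})

test_that("junction voxels tile the cut disc; area is volume^(2/3)", {
  m <- segmentize(straight_3sec(nseg = 20L))
  map <- set_solve_type(m, "s1", 3L,
                        map = set_solve_type(m, dimension = 1L))
  hm <- hybrid_model(m, map, dx = 0.25)
  jj <- hm$junctions[[1L]]
  expect_length(jj, 1L)
  j <- jj[[1L]]
  g <- hm$comps[[1L]]$grid
  # voxels lie on the cut plane at x = 10
  ctr <- voxel_centers(g)[j$voxels, , drop = FALSE]
  expect_true(all(abs(ctr[, 1] - 10) <= 0.25))
  # count comparable to disc area / dx^2 (within one voxel ring)
  n_disc <- pi * 1^2 / 0.25^2
  expect_gt(length(j$voxels), n_disc - 2 * pi / 0.25)
  expect_lt(length(j$voxels), 2 * (n_disc + 2 * pi / 0.25))
  expect_equal(j$area, g$vol[j$voxels]^(2 / 3), tolerance = 1e-12)
  expect_equal(j$dist, rep(0.25 / 2 + j$dist[1] - 0.125, length(j$voxels)),
               tolerance = 1e-12)
  # full interior voxel: area = dx^2
  full <- which(g$vol[j$voxels] == 0.25^3)
  if (length(full)) expect_equal(j$area[full][1], 0.25^2)
})

test_that("junction exchange is antisymmetric and vanishes at equilibrium", {
  m <- segmentize(straight_3sec(nseg = 20L))
  map <- set_solve_type(m, "s1", 3L, map = set_solve_type(m, dimension = 1L))
  hm <- hybrid_model(m, map, dx = 0.25, initial = 1)
  ex <- junction_exchange(hm$junctions[[1L]], hm$cable, hm$comps[[1L]]$u,
                          hm$comps[[1L]]$grid, d = 1, dt = 0.025)
  expect_equal(ex$u, hm$comps[[1L]]$u)          # equal concentrations
  expect_equal(ex$cable$u, hm$cable$u)
  # gradient case: 1D mass delta = -(3D mass delta) exactly
  hm2 <- hybrid_model(m, map, dx = 0.25,
                      initial = function(sec, x) as.numeric(sec == "s2"))
  g <- hm2$comps[[1L]]$grid
  m3_0 <- sum(hm2$comps[[1L]]$u * g$vol)
  m1_0 <- sum(hm2$cable$u * hm2$cable$vol)
  ex2 <- junction_exchange(hm2$junctions[[1L]], hm2$cable, hm2$comps[[1L]]$u,
                           g, d = 1, dt = 0.025)
  d3 <- sum(ex2$u * g$vol) - m3_0
  d1 <- sum(ex2$cable$u * hm2$cable$vol) - m1_0
  expect_equal(d3, -d1, tolerance = 1e-12 * abs(d3))
  expect_gt(d3, 0)  # mass flows toward the empty 3D side
})

test_that("1D cable diffusion conserves mass and matches the erf solution", {
  m <- segmentize(straight_3sec(nseg = 102L, L = 153))
  cab <- cable_state(m, d = 1,
                     initial = function(sec, x) {
                       xs <- c(s1 = 0, s2 = 51, s3 = 102)[sec] + 51 * x
                       as.numeric(xs > 70 & xs < 83)
                     })
  m0 <- sum(cab$u * cab$vol)
  cab <- step_1d_diffusion(cab, 0.025, nsteps = 2000L)
  expect_equal(sum(cab$u * cab$vol), m0, tolerance = 1e-12)
  x <- c(s1 = 0, s2 = 51, s3 = 102)[cab$segs$sec] +
    51 * (cab$segs$x0 + cab$segs$x1) / 2
  exact <- green1d(x, 50, 1, 70, 83, domain = c(0, 153))
  # backward-Euler 1D solver: O(dt) error ~2e-4, far below the ~1e-3 3D
  # error of the same problem (the hybrid study's reference behavior)
  expect_lt(max(abs(cab$u - exact)), 5e-4)
  # uniform state is a fixed point
  cab2 <- cable_state(m, d = 1, initial = 0.7)
  cab2 <- step_1d_diffusion(cab2, 0.1, 5L)
  expect_lt(max(abs(cab2$u - 0.7)), 1e-12)
})

test_that("junction-free hybrid equals pure per-domain stepping", {
  m <- segmentize(straight_3sec(nseg = 10L))
  map <- set_solve_type(m, dimension = 3L)
  hm <- hybrid_model(m, map, dx = 0.5,
                     initial = function(sec, x) as.numeric(sec == "s2"))
  u0 <- hm$comps[[1L]]$u
  hm2 <- hybrid_step(hm, 10L)
  direct <- dg_adi_step(u0, hm$comps[[1L]]$grid, hm$comps[[1L]]$lines,
                        1, 0.025, 10L)
  expect_equal(hm2$comps[[1L]]$u, direct, tolerance = 1e-14)
})

test_that("hybrid models conserve mass to roundoff over many steps", {
  m <- segmentize(straight_3sec(nseg = 20L))
  for (mode in list(c("s1"), c("s1", "s3"))) {
    map <- set_solve_type(m, mode, 3L, map = set_solve_type(m, dimension = 1L))
    hm <- hybrid_model(m, map, dx = 0.25,
                       initial = function(sec, x) as.numeric(sec == "s1"))
    m0 <- hybrid_mass(hm)
    hm <- hybrid_step(hm, 400L)
    expect_lt(abs(hybrid_mass(hm) - m0) / m0, 1e-10)
  }
  # Y-shaped join between 1D and 3D domains
  my <- segmentize(make_y(nseg = 10L))
  map <- set_solve_type(my, "trunk", 3L,
                        map = set_solve_type(my, dimension = 1L))
  hmy <- hybrid_model(my, map, dx = 0.25,
                      initial = function(sec, x) as.numeric(sec == "trunk"))
  m0 <- hybrid_mass(hmy)
  hmy <- hybrid_step(hmy, 400L)
  expect_lt(abs(hybrid_mass(hmy) - m0) / m0, 1e-10)
})

test_that("enlarging the 3D subdomain converges hybrid to pure 3D", {
  # diffusion from a plug near the left end; observable: mean concentration
  # in the left third after 5 ms
  obs <- function(mode) {
    m <- segmentize(straight_3sec(nseg = 20L))
    map <- if (identical(mode, "all3")) set_solve_type(m, dimension = 3L)
    else set_solve_type(m, mode, 3L, map = set_solve_type(m, dimension = 1L))
    hm <- hybrid_model(m, map, dx = 0.25,
                       initial = function(sec, x) as.numeric(sec == "s1" & x < 0.5))
    hm <- hybrid_step(hm, 200L)
    p <- hybrid_profile(hm)
    mean(p$conc[p$x < 10])
  }
  o_small <- obs("s1")                 # 3D only on the region of interest
  o_big <- obs(c("s1", "s2"))          # expanded 3D region
  o_all <- obs("all3")                 # fully 3D
  expect_lt(abs(o_big - o_all), abs(o_small - o_all) + 1e-9)
  expect_lt(abs(o_big - o_all) / o_all, 0.01)
})
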