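test_that("grid-aligned cylinder volume converges to 5*pi", {
  errs <- vapply(c(0.5, 0.25, 0.125), function(dx) {
    g <- voxelize(make_cylinder(L = 5, d = 2), dx, vr = 2L)
    abs(g$totals$volume - 5 * pi)
  }, 0)
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.05)
})

test_that("sphere volume is within 5% at dx = r/10", {
  r <- 2
  csg <- structure(list(rxd3d:::csg_sphere(c(0, 0, 0), r, seg = 1L)),
                   class = "rxd_csg",
                   segments = data.frame(id = 1L, sec = "s", seg = 0L,
                                         path_center = 0))
  g <- voxelize(csg, r / 10, vr = 1L)
  expect_equal(g$totals$volume, 4 / 3 * pi * r^3, tolerance = 0.05)
})

test_that("voxels are stored sparsely with never-zero volume fractions", {
  g <- voxelize(make_y(), 0.25)
  expect_true(all(g$frac > 0))
  expect_true(all(g$frac <= 1))
  expect_true(all(g$frac[!g$surface] == 1))
  expect_true(all(g$area[!g$surface] == 0))
  # memory proportional to the cell: far fewer voxels than the bounding box
  bb <- apply(g$keys, 2, function(k) diff(range(k)) + 1)
  expect_lt(nrow(g$keys) / prod(bb), 0.5)
})

test_that("merging a duplicated part is idempotent", {
  csg <- build_csg(make_cylinder(L = 5, d = 2))
  params <- grid_params(0.25)
  origin <- rxd3d:::csg_global_origin(csg, params)
  part <- voxelize_object(csg[[1L]], params, origin)
  g1 <- merge_meshes(list(part), csg, params, origin)
  g2 <- merge_meshes(list(part, part), csg, params, origin)
  expect_identical(g1$keys, g2$keys)
  expect_identical(g1$frac, g2$frac)
  expect_identical(g1$area, g2$area)
})

test_that("stepped cylinder: aligned segment boundaries, closed surface", {
  m <- make_stepped()
  g <- voxelize(m, 0.25)
  segs <- g$segments
  # project surface voxels of each big-cylinder segment; x-extents must
  # stay within the analytic boundaries at 5k/9 um
  xc <- voxel_centers(g)[, 1]
  for (k in 0:8) {
    id <- segs$id[segs$sec == "big" & segs$seg == k]
    sel <- g$seg == id
    expect_true(all(xc[sel] >= 5 * k / 9 - g$dx &
                    xc[sel] <= 5 * (k + 1) / 9 + g$dx))
  }
  for (k in 0:4) {
    id <- segs$id[segs$sec == "small" & segs$seg == k]
    sel <- g$seg == id & xc > 5.55  # beyond the join cone region
    if (!any(sel)) next
    expect_true(all(xc[sel] >= 5 + k - g$dx & xc[sel] <= 6 + k + g$dx))
  }
  # surface closure: no interior voxel 6-adjacent to an unstored position
  keyset <- g$enc
  for (d6 in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))) {
    nb <- rxd3d:::enc_key(g$keys[, 1] + d6[1], g$keys[, 2] + d6[2],
                          g$keys[, 3] + d6[3])
    missing_nb <- !(nb %in% keyset)
    expect_true(all(g$surface[missing_nb]))
  }
})

test_that("partial volume counts boundary test points as inside", {
  # half-space x < c bisecting the voxel through the middle lattice plane:
  # 2 of 3 lattice planes inside at VR = 2 -> fraction 2/3
  m <- make_cylinder(L = 8, d = 8)
  g <- voxelize(m, 1, vr = 2L)
  # use the flat end face at x = 4: voxel [4,5] has its x=4 face on the cap
  ctr <- voxel_centers(g)
  sel <- which(g$surface & abs(ctr[, 2]) < 1 & abs(ctr[, 3]) < 1 &
               ctr[, 1] > 4 & ctr[, 1] < 5)
  expect_true(length(sel) >= 1L)
  expect_true(all(abs(g$frac[sel] - 1 / 3) < 1e-12))
  # VR = 1: corner counting gives 1/2 on the same voxels
  f1 <- partial_volumes(g, vr = 1L)
  expect_true(all(abs(f1[sel] - 0.5) < 1e-12))
})

test_that("higher VR reduces volume error on average", {
  ori <- random_orientations(12, seed = 9)
  err <- function(vr) {
    mean(vapply(seq_len(nrow(ori)), function(i) {
      g <- voxelize(make_cylinder(L = 5, d = 2, phi = ori$phi[i],
                                  theta = ori$theta[i]), 0.25, vr = vr)
      abs(g$totals$volume - 5 * pi)
    }, 0))
  }
  expect_lt(err(4L), err(1L))
})

test_that("marching-cubes area is exact for axis-aligned planar cuts", {
  # mid-edge cut: corner distances -dx/2 inside, +dx/2 outside
  cd <- matrix(rep(c(-0.5, -0.5, -0.5, -0.5, 0.5, 0.5, 0.5, 0.5), 2),
               2, 8, byrow = TRUE)
  expect_equal(rxd3d:::mc_areas(cd), c(1, 1))
  # flat end face of a coarse cylinder: per-voxel area dx^2 exactly
  g <- voxelize(make_cylinder(L = 8, d = 8), 1, vr = 1L)
  ctr <- voxel_centers(g)
  sel <- which(g$surface & abs(ctr[, 2]) < 1 & abs(ctr[, 3]) < 1 &
               ctr[, 1] > 4 & ctr[, 1] < 5)
  expect_true(all(abs(g$area[sel] - 1) < 1e-9))
})

test_that("cylinder surface area converges toward 12*pi from below", {
  a <- vapply(c(0.5, 0.25, 0.125), function(dx) {
    voxelize(make_cylinder(L = 5, d = 2), dx)$totals$area
  }, 0)
  expect_true(all(diff(abs(a - 12 * pi)) < 0))
  expect_lt(abs(a[3] - 12 * pi) / (12 * pi), 0.02)
  # convex solid: marching-cubes areas underestimate
  ori <- random_orientations(10, seed = 4)
  under <- vapply(seq_len(10), function(i) {
    voxelize(make_cylinder(phi = ori$phi[i], theta = ori$theta[i]),
             0.25, vr = 1L)$totals$area < 12 * pi
  }, TRUE)
  expect_gte(sum(under), 9L)
})

test_that("marching cubes rejects voxels without a sign change", {
  cd <- matrix(-1, 1, 8)
  expect_error(rxd3d:::mc_areas(cd), "same side")
})

test_that("grid export round-trips", {
  g <- voxelize(make_y(), 0.5)
  td <- withr::local_tempdir()
  export_grid(g, file.path(td, "mesh.tsv"), format = "table")
  tab <- utils::read.delim(file.path(td, "mesh.tsv"))
  expect_equal(nrow(tab), nrow(g$keys))
  pngdir <- file.path(td, "stack")
  export_grid(g, pngdir, format = "png_stack")
  keys <- import_png_stack(pngdir)
  off <- apply(g$keys, 2, min)
  orig <- sweep(g$keys, 2, off)
  orig <- orig[order(rxd3d:::enc_key(orig[, 1], orig[, 2], orig[, 3])), ]
  expect_equal(unname(keys), unname(orig))
  expect_error(export_grid(structure(list(keys = matrix(integer(), 0, 3)),
                                     class = "rxd_grid"), td), "empty")
})

test_that("voxel count for the branch-point geometry is reproducible", {
  g <- voxelize(make_y(), 0.25)
  g2 <- voxelize(make_y(), 0.25)
  expect_identical(g$enc, g2$enc)
})

test_that("fractional volumes beat naive full-voxel counting", {
  ori <- random_orientations(10, seed = 21)
  for (dx in c(0.5, 0.25)) {
    err_frac <- err_naive <- naive <- numeric(10)
    for (i in 1:10) {
      g <- voxelize(make_cylinder(phi = ori$phi[i], theta = ori$theta[i]),
                    dx, vr = 1L)
      naive[i] <- nrow(g$keys) * dx^3
      err_naive[i] <- abs(naive[i] - 5 * pi)
      err_frac[i] <- abs(g$totals$volume - 5 * pi)
    }
    expect_true(all(naive > 5 * pi))          # full counting overestimates
    expect_lt(mean(err_frac), mean(err_naive))
  }
})
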