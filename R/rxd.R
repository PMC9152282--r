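#' Physical constants and unit conventions
#'
#' Concentrations are mM, volumes um^3, time ms, diffusion constants
#' um^2/ms. One mM.um^3 equals 1e-18 mol, i.e. 602214.076 molecules.
#' @export
rxd_constants <- function() {
  list(FARADAY = 96485,              # C/mol
       N_A = 6.02214076e23,          # /mol
       MOLECULES_PER_MM_UM3 = 6.02214076e5,
       MOL_PER_MM_UM3 = 1e-18)
}

#' Define a chemical species, parameter, or state
#'
#' `species` react and diffuse; `state` variables react but do not diffuse;
#' `parameter` values change with location but are never updated.
#'
#' @param name species name.
#' @param d diffusion constant, um^2/ms.
#' @param z valence (charge), used to convert membrane currents.
#' @param initial initial concentration: a constant (mM) or a function
#'   `f(x, y, z)` of voxel-center position returning mM.
#' @param kind one of `"species"`, `"parameter"`, `"state"`.
#' @export
species <- function(name, d = 0, z = 0L, initial = 0,
                    kind = c("species", "parameter", "state")) {
  structure(list(name = name, d = d, z = z, initial = initial,
                 kind = match.arg(kind)), class = "rxd_species")
}

#' Define a reaction by its rate contributions
#'
#' @param rate function taking a named list of concentration vectors (one per
#'   species, aligned with voxel storage order) and returning the scalar
#'   reaction velocity vector (mM/ms).
#' @param stoich named numeric vector: change of each species per unit
#'   velocity (e.g. `c(a = -1, b = +1)`).
#' @param voxels optional integer vector restricting the reaction to a
#'   subset of voxels (a region restriction).
#' @export
reaction <- function(rate, stoich, voxels = NULL) {
  structure(list(rate = rate, stoich = stoich, voxels = voxels),
            class = "rxd_reaction")
}

#' Mass-based point flux at a voxel
#'
#' The flux is specified in molecules per unit time so the same amount of
#' substance enters the cell regardless of the spatial discretization.
#'
#' @param species species name.
#' @param voxel target voxel storage index.
#' @param g production rate (molecules per `units`).
#' @param units `"ms"` (default) or `"s"`.
#' @export
point_flux <- function(species, voxel, g, units = c("ms", "s")) {
  units <- match.arg(units)
  structure(list(species = species, voxel = as.integer(voxel),
                 g = if (units == "s") g / 1000 else g),  # molecules/ms
            class = "rxd_point_flux")
}

#' Assemble a 3D reaction-diffusion model on a voxel grid
#'
#' @param grid an `rxd_grid`.
#' @param species list of [species()] definitions.
#' @param reactions list of [reaction()]s.
#' @param fluxes list of [point_flux()]es.
#' @param dt fixed time step, ms.
#' @param feedback `"surface"` (default) or `"all"`: which voxels contribute
#'   to the per-segment concentrations reported by [segment_feedback()].
#' @param newton_tol,newton_maxit implicit-reaction Newton controls.
#' @return an `rxd_model` with per-voxel concentration vectors in
#'   `$conc[[name]]`, the line index in `$lines`, and bookkeeping fields.
#' @export
rxd_model <- function(grid, species = list(), reactions = list(),
                      fluxes = list(), dt = 0.025,
                      feedback = c("surface", "all"),
                      newton_tol = 1e-12, newton_maxit = 20L) {
  stopifnot(inherits(grid, "rxd_grid"), dt > 0)
  feedback <- match.arg(feedback)
  if (inherits(species, "rxd_species")) species <- list(species)
  names(species) <- vapply(species, `[[`, "", "name")
  ctr <- voxel_centers(grid)
  conc <- lapply(species, function(sp) {
    if (is.function(sp$initial)) sp$initial(ctr[, 1], ctr[, 2], ctr[, 3])
    else rep(sp$initial, nrow(ctr))
  })
  structure(list(grid = grid, species = species, reactions = reactions,
                 fluxes = fluxes, dt = dt, t = 0, feedback = feedback,
                 newton_tol = newton_tol, newton_maxit = as.integer(newton_maxit),
                 lines = build_lines(grid), conc = conc),
            class = "rxd_model")
}

#' Decompose a voxel grid into contiguous lines per axis
#'
#' For each axis, stored voxels are grouped into maximal contiguous runs
#' (found from the sorted (i, j, k) keys, the vectorized equivalent of
#' backtracking from a seed voxel through the location hash). These lines are
#' the tridiagonal systems of the ADI sweeps; every stored voxel appears in
#' exactly one line per axis.
#'
#' @param grid an `rxd_grid`.
#' @return list with components `x`, `y`, `z`, each holding 0-based `idx`
#'   (concatenated voxel storage indices) and `ptr` (line offsets).
#' @export
build_lines <- function(grid) {
  if (!nrow(grid$keys)) stop("empty grid")
  k <- grid$keys
  one_axis <- function(run_col, o1, o2) {
    ord <- order(k[, o2], k[, o1], k[, run_col])
    runc <- k[ord, run_col]
    brk <- c(TRUE, diff(runc) != 1L |
               diff(k[ord, o1]) != 0L | diff(k[ord, o2]) != 0L)
    list(idx = as.integer(ord - 1L), ptr = as.integer(c(which(brk), length(ord) + 1L) - 1L))
  }
  list(x = one_axis(1L, 2L, 3L),
       y = one_axis(2L, 1L, 3L),
       z = one_axis(3L, 1L, 2L))
}

#' One Douglas-Gunn ADI diffusion step
#'
#' Advances a concentration field by `dt` of pure diffusion using three
#' implicit tridiagonal sweeps (x, then y, then z) with implicit weight 1/2
#' on the swept direction and explicit correction for the others
#' (Crank-Nicolson consistent, second order). Line ends are zero-flux
#' (fully reflective membrane). Face conductances are scaled by the mean of
#' the adjacent voxels' interior volume fractions, and fluxes are divided by
#' the receiving voxel's interior volume, so mass is conserved exactly.
#'
#' @param u concentration vector (mM), voxel storage order.
#' @param grid an `rxd_grid`.
#' @param lines line index from [build_lines()].
#' @param d diffusion constant, um^2/ms.
#' @param dt time step, ms.
#' @param nsteps number of steps to take.
#' @return the advanced concentration vector.
#' @export
dg_adi_step <- function(u, grid, lines, d, dt, nsteps = 1L) {
  if (any(!is.finite(u))) stop("non-finite concentrations")
  if (d < 0) stop("diffusion constant must be >= 0")
  res <- cpp_advance(u, grid$vol, grid$frac,
                     lines$x$idx, lines$x$ptr, lines$y$idx, lines$y$ptr,
                     lines$z$idx, lines$z$ptr,
                     d, grid$dx, dt, as.integer(nsteps),
                     0L, 0, integer(), numeric(), 0L,
                     integer(), 0L, numeric(), 0.5, FALSE,
                     integer(), FALSE, integer())
  if (any(!is.finite(res$u))) stop("non-finite concentrations after step")
  res$u
}

#' Implicit reaction / point-flux step
#'
#' Backward-Euler solve of the local reaction ODEs at every voxel (Newton
#' iteration on the local reaction Jacobian, tolerance and iteration cap from
#' the model), applied before diffusion in each operator-split step. Point
#' fluxes convert molecules/ms to mM/ms through the voxel's interior volume.
#' Parameters are never changed; states react but do not diffuse.
#'
#' @param model an `rxd_model`.
#' @param dt step, ms (defaults to the model dt).
#' @return the model with updated concentrations.
#' @export
reaction_step <- function(model, dt = model$dt) {
  conc <- model$conc
  kinds <- vapply(model$species, `[[`, "", "kind")
  dyn <- names(kinds)[kinds != "parameter"]
  if (length(model$reactions) && length(dyn)) {
    nv <- nrow(model$grid$keys)
    u0 <- conc
    u <- conc
    rate_all <- function(u) {
      du <- stats::setNames(rep(list(numeric(nv)), length(dyn)), dyn)
      for (rx in model$reactions) {
        v <- rx$rate(u)
        for (sp in names(rx$stoich)) {
          if (!sp %in% dyn) next
          if (is.null(rx$voxels)) du[[sp]] <- du[[sp]] + rx$stoich[[sp]] * v
          else du[[sp]][rx$voxels] <- du[[sp]][rx$voxels] +
              rx$stoich[[sp]] * (if (length(v) == 1L) v else v[rx$voxels])
        }
      }
      du
    }
    for (it in seq_len(model$newton_maxit)) {
      f <- rate_all(u)
      # residual g_s = u_s - u0_s - dt * f_s(u); Newton with a numerically
      # diagonal-plus-coupling Jacobian solved per voxel
      res <- lapply(dyn, function(sp) u[[sp]] - u0[[sp]] - dt * f[[sp]])
      names(res) <- dyn
      maxres <- max(vapply(res, function(r) max(abs(r)), 0))
      if (maxres < model$newton_tol) break
      if (length(dyn) == 1L) {
        sp <- dyn[[1L]]
        eps <- pmax(1e-7, 1e-7 * abs(u[[sp]]))
        up <- u; up[[sp]] <- u[[sp]] + eps
        dfdu <- (rate_all(up)[[sp]] - f[[sp]]) / eps
        u[[sp]] <- u[[sp]] - res[[sp]] / (1 - dt * dfdu)
      } else {
        ns <- length(dyn)
        J <- array(0, c(nv, ns, ns))
        for (b in seq_len(ns)) {
          sp <- dyn[[b]]
          eps <- pmax(1e-7, 1e-7 * abs(u[[sp]]))
          up <- u; up[[sp]] <- u[[sp]] + eps
          fp <- rate_all(up)
          for (a in seq_len(ns))
            J[, a, b] <- (a == b) - dt * (fp[[dyn[[a]]]] - f[[dyn[[a]]]]) / eps
        }
        for (v in seq_len(nv)) {
          rv <- vapply(dyn, function(sp) res[[sp]][v], 0)
          if (all(rv == 0)) next
          dv <- tryCatch(solve(J[v, , ], rv), error = function(e)
            stop("reaction Newton failed at voxel ", v))
          for (a in seq_len(ns)) u[[dyn[[a]]]][v] <- u[[dyn[[a]]]][v] - dv[a]
        }
      }
      if (it == model$newton_maxit) {
        f <- rate_all(u)
        res <- lapply(dyn, function(sp) u[[sp]] - u0[[sp]] - dt * f[[sp]])
        if (max(vapply(res, function(r) max(abs(r)), 0)) >= model$newton_tol * 100)
          stop("reaction Newton did not converge (max residual at voxel ",
               which.max(abs(res[[1L]])), ")")
      }
    }
    conc <- u
  }
  for (fl in model$fluxes) {
    v <- fl$voxel
    conc[[fl$species]][v] <- conc[[fl$species]][v] +
      fl$g / rxd_constants()$MOLECULES_PER_MM_UM3 / model$grid$vol[v] * dt
  }
  model$conc <- conc
  model
}

#' Advance a model by full operator-split steps
#'
#' Each step applies reactions and point fluxes implicitly first, then
#' diffusion with DG-ADI (species diffuse; states and parameters do not).
#'
#' @param model an `rxd_model`.
#' @param nsteps number of dt-steps.
#' @return the advanced model.
#' @export
sim_advance <- function(model, nsteps = 1L) {
  fast <- length(model$reactions) == 0L && length(model$fluxes) == 0L
  for (s in seq_len(if (fast) 1L else nsteps)) {
    if (!fast) model <- reaction_step(model)
    for (nm in names(model$species)) {
      sp <- model$species[[nm]]
      if (sp$kind != "species" || sp$d <= 0) next
      model$conc[[nm]] <- dg_adi_step(model$conc[[nm]], model$grid,
                                      model$lines, sp$d, model$dt,
                                      nsteps = if (fast) nsteps else 1L)
    }
    model$t <- model$t + model$dt * (if (fast) nsteps else 1L)
  }
  model
}

#' Distribute a segment membrane current over its surface voxels
#'
#' A mechanism current generated by an electrical segment is split across
#' the segment's surface voxels proportionally to voxel surface area, then
#' converted to concentration rates of change using Faraday's constant, the
#' ion charge, and each voxel's interior volume.
#'
#' @param i_seg segment current in nA (NEURON convention: inward current is
#'   negative and increases interior concentration).
#' @param grid an `rxd_grid`.
#' @param seg segment id.
#' @param z ion valence (nonzero).
#' @return list with `voxels` (storage indices) and `rate` (mM/ms per voxel).
#' @export
distribute_segment_current <- function(i_seg, grid, seg, z) {
  vox <- which(grid$seg == seg & grid$area > 0)
  if (!length(vox)) stop("segment ", seg, " has no surface voxels")
  share <- grid$area[vox] / sum(grid$area[vox])
  # nA -> mol/ms: 1 nA = 1e-9 C/s = 1e-12 C/ms; / (z*F) mol/ms
  mol_per_ms <- -i_seg * 1e-12 / (z * rxd_constants()$FARADAY)
  # mol/ms -> mM um^3/ms: / 1e-18; per voxel divide by interior volume
  list(voxels = vox,
       rate = mol_per_ms * 1e18 * share / grid$vol[vox])
}

#' Per-segment concentrations reported back to the 1D model
#'
#' Volume-weighted mean concentration over each segment's surface voxels
#' (`mode = "surface"`, the default) or over all its voxels
#' (`mode = "all"`, which mitigates artificially high surface concentrations
#' when few 3D voxels exchange with one segment).
#'
#' @param grid an `rxd_grid`.
#' @param u concentration vector.
#' @param mode `"surface"` or `"all"`.
#' @return named numeric vector of segment concentrations (mM), indexed by
#'   segment id.
#' @export
segment_feedback <- function(grid, u, mode = c("surface", "all")) {
  mode <- match.arg(mode)
  sel <- if (mode == "surface") grid$surface & grid$area > 0 else
    rep(TRUE, length(u))
  w <- grid$vol * sel
  num <- tapply(u * w, grid$seg, sum)
  den <- tapply(w, grid$seg, sum)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Total mass of a concentration field
#'
#' @param u concentration vector (mM).
#' @param grid an `rxd_grid`.
#' @param units `"mol"` or `"molecules"`.
#' @return total mass (sum of concentration times interior volume).
#' @export
total_mass <- function(u, grid, units = c("mol", "molecules")) {
  units <- match.arg(units)
  m <- sum(u * grid$vol)  # mM um^3
  k <- rxd_constants()
  if (units == "mol") m * k$MOL_PER_MM_UM3 else m * k$MOLECULES_PER_MM_UM3
}
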