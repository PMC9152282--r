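#' Nernst equilibrium potential
#'
#' `E = (RT / zF) ln(c_out / c_in)`, in mV.
#'
#' @param c_in,c_out intra/extracellular concentrations, mM (positive).
#' @param z ion valence.
#' @param T_k temperature, Kelvin (default 6.3 degrees C, the squid-axon
#'   reference temperature of the Hodgkin-Huxley kinetics).
#' @return potential in mV.
#' @export
nernst <- function(c_in, c_out, z = 1, T_k = 273.15 + 6.3) {
  if (any(c_in <= 0) || any(c_out <= 0))
    stop("concentrations must be positive")
  R <- 8.31446
  1000 * R * T_k / (z * rxd_constants()$FARADAY) * log(c_out / c_in)
}

#' Hodgkin-Huxley membrane state
#'
#' Classic squid-axon kinetics with standard defaults: `gnabar = 0.12`,
#' `gkbar = 0.036`, `gl = 0.0003` S/cm^2, `el = -54.3` mV, `ek = -77` mV,
#' resting `v = -65` mV, `nai = 10` mM, `nao = 140` mM, 6.3 degrees C.
#' Gating variables start at their steady state for `v`. The sodium reversal
#' potential is recomputed from the concentrations via [nernst()].
#'
#' @param v initial membrane potential, mV.
#' @param area membrane area used for electrical current densities, um^2
#'   (the 1D summed-frusta lateral area of the segment, not the 3D
#'   voxelized area).
#' @param gnabar,gkbar,gl peak conductances, S/cm^2.
#' @param el leak reversal, mV; `ek` potassium reversal, mV.
#' @param nai,nao sodium concentrations, mM.
#' @param cm specific capacitance, uF/cm^2.
#' @param T_k temperature, K.
#' @return an `rxd_hh` state.
#' @export
hh_state <- function(v = -65, area, gnabar = 0.12, gkbar = 0.036,
                     gl = 0.0003, el = -54.3, ek = -77, nai = 10, nao = 140,
                     cm = 1, T_k = 273.15 + 6.3) {
  r <- hh_rates(v)
  structure(list(v = v, m = r$am / (r$am + r$bm), h = r$ah / (r$ah + r$bh),
                 n = r$an / (r$an + r$bn),
                 area = area, gnabar = gnabar, gkbar = gkbar, gl = gl,
                 el = el, ek = ek, nai = nai, nao = nao, cm = cm, T_k = T_k),
            class = "rxd_hh")
}

hh_rates <- function(v) {
  vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2),
                                 x / (exp(x / y) - 1))
  list(am = 0.1 * vtrap(-(v + 40), 10),
       bm = 4 * exp(-(v + 65) / 18),
       ah = 0.07 * exp(-(v + 65) / 20),
       bh = 1 / (1 + exp(-(v + 35) / 10)),
       an = 0.01 * vtrap(-(v + 55), 10),
       bn = 0.125 * exp(-(v + 65) / 80))
}

#' Advance the Hodgkin-Huxley state one step
#'
#' Gating variables relax analytically toward their voltage-dependent steady
#' states over `dt`; the membrane potential is then updated implicitly
#' (linearized conductances), the scheme NEURON-style fixed-step integration
#' uses. Returns the per-ion currents so sodium mass can be distributed over
#' surface voxels; by NEURON convention inward current is negative.
#'
#' @param state an `rxd_hh`.
#' @param i_inject injected current, nA (positive depolarizes).
#' @param dt step, ms.
#' @return list with the advanced `state` plus `ina`, `ik`, `il` (mA/cm^2)
#'   and `ina_nA` (total segment sodium current, nA).
#' @export
hh_advance <- function(state, i_inject = 0, dt = 0.025) {
  s <- state
  r <- hh_rates(s$v)
  relax <- function(x, a, b) {
    tau <- 1 / (a + b); inf <- a * tau
    inf + (x - inf) * exp(-dt / tau)
  }
  s$m <- relax(s$m, r$am, r$bm)
  s$h <- relax(s$h, r$ah, r$bh)
  s$n <- relax(s$n, r$an, r$bn)
  ena <- nernst(s$nai, s$nao, z = 1, T_k = s$T_k)
  # conductances in mS/cm^2 so that g*v is in uA/cm^2 and
  # dv/dt = i/cm is in mV/ms with cm in uF/cm^2
  gna <- 1e3 * s$gnabar * s$m^3 * s$h
  gk <- 1e3 * s$gkbar * s$n^4
  gl <- 1e3 * s$gl
  area_cm2 <- s$area * 1e-8
  iinj <- i_inject * 1e-3 / area_cm2           # nA -> uA/cm^2
  gtot <- gna + gk + gl
  esum <- gna * ena + gk * s$ek + gl * s$el
  # implicit voltage update: cm (v' - v)/dt = esum + iinj - gtot v'
  s$v <- (s$v + dt / s$cm * (esum + iinj)) / (1 + dt / s$cm * gtot)
  ina <- gna * (s$v - ena) * 1e-3              # mA/cm^2
  list(state = s, ina = ina, ik = gk * (s$v - s$ek) * 1e-3,
       il = gl * (s$v - s$el) * 1e-3, ina_nA = ina * area_cm2 * 1e6)
}

#' Event-driven exponential synaptic flux
#'
#' The production rate `g` (molecules/ms) jumps by the event weight at each
#' event time and decays exponentially with time constant `tau` in between.
#' The mass delivered over a step is the exact integral of `g`, so the total
#' amount of substance entering the cell is independent of dx and dt (it
#' converges to `weight * tau` per event).
#'
#' @param tau decay time constant, ms.
#' @param voxel target surface voxel storage index.
#' @param events data.frame with `time` (ms) and `weight` (molecules/ms),
#'   time-ordered.
#' @param g0 initial rate.
#' @return an `rxd_syn` state.
#' @export
syn_flux <- function(tau, voxel, events = data.frame(time = numeric(),
                                                     weight = numeric()),
                     g0 = 0) {
  stopifnot(tau > 0, g0 >= 0)
  if (is.unsorted(events$time)) stop("events must be time-ordered")
  structure(list(tau = tau, voxel = as.integer(voxel), events = events,
                 g = g0, t = 0, next_ev = 1L), class = "rxd_syn")
}

#' Advance the synaptic flux one step
#'
#' @param flux an `rxd_syn`.
#' @param dt step, ms.
#' @param grid optional `rxd_grid`; when supplied, the target voxel must have
#'   strictly positive surface area and the delivered mass is converted to a
#'   concentration increment through the voxel's interior volume.
#' @return list with advanced `flux`, `mass_molecules` delivered during the
#'   step, and (with a grid) `dconc` in mM for the target voxel.
#' @export
syn_advance <- function(flux, dt, grid = NULL) {
  if (!is.null(grid) && grid$area[flux$voxel] <= 0)
    stop("synaptic flux targets a voxel with zero surface area")
  t0 <- flux$t; t1 <- flux$t + dt
  mass <- 0; g <- flux$g; tcur <- t0; ev <- flux$next_ev
  evs <- flux$events
  repeat {
    tev <- if (ev <= nrow(evs)) evs$time[ev] else Inf
    tstop <- min(tev, t1)
    if (tstop > tcur) {
      seg <- tstop - tcur
      mass <- mass + g * flux$tau * (1 - exp(-seg / flux$tau))
      g <- g * exp(-seg / flux$tau)
      tcur <- tstop
    }
    if (tev <= t1) {
      g <- g + evs$weight[ev]
      ev <- ev + 1L
    } else break
  }
  flux$g <- g; flux$t <- t1; flux$next_ev <- ev
  out <- list(flux = flux, mass_molecules = mass)
  if (!is.null(grid))
    out$dconc <- mass / rxd_constants()$MOLECULES_PER_MM_UM3 /
      grid$vol[flux$voxel]
  out
}
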