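#' Build a model from a structured config file
#'
#' Reads a YAML description of a reaction-diffusion model:
#'
#' ```yaml
#' morphology: cell.swc        # or fixture: y | cylinder | stepped | spiny
#' solver: {dx: 0.25, dt: 0.025, vr: 2, sr: 1, feedback: surface}
#' species:
#'   - {name: ca, d: 0.25, z: 2, initial: 0.0001}
#' reactions:
#'   - {rate: "-ca * (1 - ca) * (0.25 - ca)", stoich: {ca: 1}}
#' regions:
#'   - {sections: [trunk], species: ca, initial: 1.0}
#' solve_type:
#'   - {sections: [br1, br2], dimension: 1}
#' ```
#'
#' Rate expressions are R expressions over species names, evaluated per
#' voxel. Region entries override per-species initial concentrations on the
#' voxels of the listed sections.
#'
#' @param path YAML file path.
#' @return for a pure-3D config, an `rxd_model`; when `solve_type` marks
#'   sections 1D, an `rxd_hybrid` (single species, no reactions).
#' @export
read_model_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the yaml package")
  cfg <- yaml::read_yaml(path)
  fx <- cfg$fixture %||% "cylinder"
  if (isTRUE(fx)) fx <- "y"  # YAML 1.1 parses a bare `y` as boolean true
  m <- if (!is.null(cfg$morphology)) read_swc(cfg$morphology)
  else switch(as.character(fx),
              cylinder = make_cylinder(), y = make_y(),
              stepped = make_stepped(), spiny = make_spiny(),
              stop("unknown fixture '", fx, "'"))
  m <- segmentize(m)
  sol <- cfg$solver %||% list()
  dx <- sol$dx %||% 0.25
  dt <- sol$dt %||% 0.025
  sp <- lapply(cfg$species %||% list(), function(s)
    species(s$name, d = s$d %||% 0, z = s$z %||% 0L,
            initial = s$initial %||% 0, kind = s$kind %||% "species"))
  rx <- lapply(cfg$reactions %||% list(), function(r) {
    expr <- parse(text = r$rate)[[1L]]
    reaction(rate = function(st) eval(expr, st),
             stoich = unlist(r$stoich))
  })
  if (!is.null(cfg$solve_type)) {
    map <- set_solve_type(m, dimension = 3L)
    for (st in cfg$solve_type)
      map <- set_solve_type(m, st$sections, as.integer(st$dimension),
                            map = map)
    if (any(map == 1L)) {
      if (length(sp) != 1L || length(rx))
        stop("hybrid configs support a single diffusing species")
      init <- region_initial_fun(cfg, sp[[1L]])
      return(hybrid_model(m, map, dx = dx, d = sp[[1L]]$d, initial = init,
                          dt = dt, vr = as.integer(sol$vr %||% 2L),
                          sr = as.integer(sol$sr %||% 1L)))
    }
  }
  g <- voxelize(m, dx, vr = as.integer(sol$vr %||% 2L),
                sr = as.integer(sol$sr %||% 1L))
  mod <- rxd_model(g, species = sp, reactions = rx, dt = dt,
                   feedback = sol$feedback %||% "surface")
  # region overrides
  secs <- g$segments$sec[match(g$seg, g$segments$id)]
  for (rg in cfg$regions %||% list()) {
    sel <- secs %in% rg$sections
    mod$conc[[rg$species]][sel] <- rg$initial
  }
  mod
}

region_initial_fun <- function(cfg, sp) {
  regions <- cfg$regions %||% list()
  base <- if (is.numeric(sp$initial)) sp$initial else 0
  function(sec, x) {
    out <- rep(base, length(sec))
    for (rg in regions) out[sec %in% rg$sections] <- rg$initial
    out
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
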